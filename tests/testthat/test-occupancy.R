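delta_train_reads <- function(positions, k0, chrom = "chr1", read_length = 36) {
  # plus reads starting at p; minus reads whose 5' start is p + k0
  dplyr::bind_rows(
    tibble::tibble(chrom = chrom, start = positions,
                   end = positions + read_length, seq = "N", score = 1000L,
                   strand = "+"),
    tibble::tibble(chrom = chrom, start = positions + k0 - read_length + 1L,
                   end = positions + k0 + 1L, seq = "N", score = 1000L,
                   strand = "-")
  )
}

test_that("start-site densities count 5' ends per strand", {
  reads <- tibble::tibble(chrom = "chr1", start = c(10L, 10L, 20L),
                          end = c(46L, 46L, 56L), seq = "N", score = 1000L,
                          strand = c("+", "+", "-"))
  d <- start_site_density(reads, c(chr1 = 100L))
  expect_equal(sum(d$density$chr1$plus), 2L)
  expect_equal(d$density$chr1$plus[11], 2L)
  expect_equal(d$density$chr1$minus[56], 1L)  # 5' start of a minus read = end-1
})

test_that("identical strand shapes at a fixed offset give r = 1 and L = offset", {
  set.seed(401)
  pos <- sort(sample.int(400000, 4000))
  reads <- delta_train_reads(pos, k0 = 180L)
  d <- start_site_density(reads, c(chr1 = 401000L))
  est <- estimate_fragment_size(d, max_offset = 400, read_length = 36)
  expect_equal(est$L, 180L)
  expect_gt(est$curve$r[est$curve$offset == 180], 0.99)
})

test_that("fragment size is recovered from simulated site data within 10 bp", {
  set.seed(402)
  clade <- evolve_clade(60000, c(sp = 0))
  landscape <- binding_landscape(n_sites = 20, fragment_size = 200)
  chip <- simulate_chip_reads(clade, landscape, n_reads = 2000,
                              background_frac = 0.1, species = "reference")
  d <- start_site_density(chip$reads$reference, c(chr1 = 60000L))
  est <- estimate_fragment_size(d, max_offset = 400, read_length = 36)
  expect_lte(abs(est$L - 200L), 10L)
})

test_that("smoothed-derivative zero crossing matches an argmax-style oracle", {
  # the same L as smoothing r(k) and taking its first local maximum
  set.seed(403)
  clade <- evolve_clade(60000, c(sp = 0))
  chip <- simulate_chip_reads(clade, binding_landscape(n_sites = 30),
                              n_reads = 3000, species = "reference")
  d <- start_site_density(chip$reads$reference, c(chr1 = 60000L))
  est <- estimate_fragment_size(d, max_offset = 400, read_length = 36)
  kern <- dnorm(seq(-40, 40), sd = 10)
  r_s <- stats::filter(est$curve$r, kern / sum(kern), sides = 2)
  first_max <- which(diff(sign(diff(r_s))) < 0)[1] + 1L
  expect_lte(abs(est$L - est$curve$offset[first_max]), 5L)
})

test_that("estimation failures raise informative errors", {
  # a cross-correlation curve that rises through the whole searched range
  # (peak beyond max_offset): minus strand is the plus strand shifted by 450
  # with a broad smooth profile, so no downward zero-crossing exists in range
  set.seed(412)
  n <- 30000L
  smooth_noise <- as.numeric(stats::filter(rnorm(n + 450L), rep(1, 300) / 300,
                                           sides = 2))
  smooth_noise[is.na(smooth_noise)] <- 0
  base <- pmax(round(30 * (1 + smooth_noise)), 0L)
  d <- structure(list(
    density = list(chr1 = list(plus = base[1:n],
                               minus = c(rep(0L, 450L), base)[1:n])),
    chrom_sizes = c(chr1 = n)), class = "start_density")
  expect_error(estimate_fragment_size(d, max_offset = 300, read_length = 36),
               class = "netdecay_estimation_error")
  reads <- delta_train_reads(c(1000L, 3000L), k0 = 180L)
  only_plus <- reads[reads$strand == "+", ]
  expect_error(
    estimate_fragment_size(start_site_density(only_plus, c(chr1 = 5000L)),
                           max_offset = 400),
    class = "netdecay_empty_error")
})

test_that("imputed density extends each start by L in the 3' direction", {
  reads <- tibble::tibble(chrom = "chr1", start = 100L, end = 136L,
                          seq = "N", score = 1000L, strand = "+")
  prof <- impute_density(reads, L = 5L, chrom_sizes = c(chr1 = 200L))
  expect_equal(which(prof$density$chr1$plus > 0), 101:105)  # [100, 105)
  minus <- tibble::tibble(chrom = "chr1", start = 100L, end = 136L,
                          seq = "N", score = 1000L, strand = "-")
  pm <- impute_density(minus, L = 5L, chrom_sizes = c(chr1 = 200L))
  expect_equal(which(pm$density$chr1$minus > 0), 132:136)   # [131, 136)
})

test_that("unnormalized density mass is conserved and additive", {
  set.seed(404)
  n <- 10000L
  mk <- function(m) tibble::tibble(
    chrom = "chr1", start = sample.int(n - 300L, m) + 100L,
    end = 0L, seq = "N", score = 1000L, strand = sample(c("+", "-"), m, TRUE)
  ) |> dplyr::mutate(end = start + 36L)
  r1 <- mk(200); r2 <- mk(150)
  L <- 50L
  p1 <- impute_density(r1, L, c(chr1 = n))
  expect_equal(sum(p1$density$chr1$plus) + sum(p1$density$chr1$minus),
               200 * L)
  p2 <- impute_density(r2, L, c(chr1 = n))
  merged <- merge_profiles(p1, p2)
  pc <- impute_density(dplyr::bind_rows(r1, r2), L, c(chr1 = n))
  expect_equal(merged$density$chr1$plus, pc$density$chr1$plus)
  expect_equal(merged$density$chr1$minus, pc$density$chr1$minus)
})

test_that("PCR-duplicate removal keeps one read per strand-specific start", {
  reads <- tibble::tibble(chrom = "chr1",
                          start = c(10L, 10L, 10L, 40L),
                          end = c(46L, 46L, 46L, 76L), seq = "N",
                          score = 1000L, strand = c("+", "+", "-", "+"))
  dd <- dedup_reads(reads)
  expect_equal(nrow(dd), 3L)  # +10 kept once, -10 distinct, +40 kept
})

test_that("mappability marks exactly the unique k-mers of the two-stranded genome", {
  # all 3-mers of 'ACGTAG' vs the repeat/palindrome cases
  g1 <- Biostrings::DNAStringSet(c(chr1 = "AAAAAA"))
  t1 <- mappability_track(g1, 3)
  expect_false(any(t1$track$chr1$plus))
  expect_false(any(t1$track$chr1$minus))
  set.seed(405)
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")))
  t2 <- mappability_track(g2, 20)
  oracle <- oracle_mappable_plus(as.character(g2[[1]]), 20)
  expect_equal(t2$track$chr1$plus[seq_along(oracle)], oracle)
  # minus track is the plus track shifted by k-1
  expect_equal(t2$track$chr1$minus[20:2000], t2$track$chr1$plus[1:1981])
})

test_that("normalization is identity on fully mappable genomes", {
  set.seed(406)
  g <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")))
  track <- mappability_track(g, 15)
  # interior positions of a random genome at k=15 are essentially all unique
  reads <- tibble::tibble(chrom = "chr1", start = c(500L, 1500L),
                          end = c(515L, 1515L), seq = "N", score = 1000L,
                          strand = c("+", "-"))
  prof <- impute_density(reads, 50L, c(chr1 = 3000L))
  norm <- normalize_density(prof, track)
  raw_sum <- prof$density$chr1$plus + prof$density$chr1$minus
  interior <- 600:1400
  expect_equal(norm$density$chr1[interior], raw_sum[interior])
})

test_that("normalization rescales by the mappable window fraction", {
  # hand-built track: half the upstream window unmappable doubles the density
  prof <- impute_density(
    tibble::tibble(chrom = "chr1", start = 100L, end = 120L, seq = "N",
                   score = 1000L, strand = "+"),
    L = 10L, chrom_sizes = c(chr1 = 300L))
  track <- structure(list(
    track = list(chr1 = list(plus = rep(c(TRUE, FALSE), 150),
                             minus = rep(TRUE, 300))),
    read_length = 20L, chrom_sizes = c(chr1 = 300L)),
    class = "mappability_track")
  norm <- normalize_density(prof, track)
  # density 1 over [100,110); windows contain 5 of 10 mappable plus starts
  expect_equal(norm$density$chr1[105], 2.0)
})

test_that("repeat-induced masks match direct window counting", {
  set.seed(407)
  base <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  dup <- paste0(substr(base, 1, 1000), substr(base, 1, 1000),
                substr(base, 1001, 3000))
  g <- Biostrings::DNAStringSet(c(chr1 = dup))
  k <- 25L; L <- 40L
  track <- mappability_track(g, k)
  reads <- tibble::tibble(chrom = "chr1", start = seq(100L, 3900L, by = 400L),
                          end = seq(100L, 3900L, by = 400L) + k, seq = "N",
                          score = 1000L, strand = "+")
  norm <- normalize_density(impute_density(reads, L, c(chr1 = 4000L)), track)
  n <- 4000L
  tp <- track$track$chr1$plus
  tm <- track$track$chr1$minus
  expected_mask <- vapply(seq_len(n), function(p) {
    wp <- sum(tp[max(1, p - L + 1):p])
    wm <- sum(tm[p:min(n, p + L - 1)])
    wp == 0 || wm == 0
  }, logical(1))
  expect_equal(norm$mask$chr1, expected_mask)
  # masked positions grow when the read length shrinks on a repeat genome
  track_small <- mappability_track(g, 15L)
  norm_small <- normalize_density(impute_density(reads, L, c(chr1 = 4000L)),
                                  track_small)
  expect_true(all(norm$mask$chr1[norm_small$mask$chr1 == FALSE] == FALSE))
  expect_gte(sum(norm_small$mask$chr1), sum(norm$mask$chr1))
})

test_that("a profile correlates perfectly with itself through an identity map", {
  set.seed(408)
  clade <- evolve_clade(30000, c(twin = 0))
  chip <- simulate_chip_reads(clade, binding_landscape(n_sites = 20),
                              n_reads = 4000, species = "reference")
  track <- mappability_track(clade$reference, 36)
  prof <- occupancy_pipeline(chip$reads$reference, track, L = 200L)
  r <- correlate_profiles(prof, prof, clade$chains$twin)
  expect_equal(r$r, 1.0)
})

test_that("independent background simulations are uncorrelated", {
  set.seed(409)
  clade <- evolve_clade(150000, c(twin = 0))
  track <- mappability_track(clade$reference, 36)
  mk <- function() {
    chip <- simulate_chip_reads(clade, binding_landscape(n_sites = 0,
                                                         fragment_size = 100),
                                n_reads = 20000, background_frac = 1,
                                species = "reference")
    occupancy_pipeline(chip$reads$reference, track, L = 100L)
  }
  r <- correlate_profiles(mk(), mk(), clade$chains$twin)
  expect_lt(abs(r$r), 0.05)
})

test_that("profile correlation rises with the shared-site fraction", {
  set.seed(410)
  clade <- evolve_clade(40000, c(twin = 0))
  track <- mappability_track(clade$reference, 36)
  glen <- 40000L
  n_sites <- 40L
  base_sites <- tibble::tibble(chrom = "chr1",
                               position = sort(sample.int(glen - 400L, n_sites) + 200L),
                               strength = 1)
  profile_for <- function(sites) {
    reads <- netdecay:::simulate_reads_one(
      clade$reference, dplyr::mutate(sites, shared = TRUE),
      binding_landscape(n_sites = nrow(sites), fragment_size = 200),
      n_reads = 8000, read_length = 36, background_frac = 0.2, jitter_sd = 20)
    occupancy_pipeline(reads, track, L = 200L)
  }
  ref_prof <- profile_for(base_sites)
  rs <- vapply(c(0, 0.5, 1), function(shared) {
    keep <- seq_len(round(n_sites * shared))
    novel <- tibble::tibble(
      chrom = "chr1",
      position = sort(sample.int(glen - 400L, n_sites - length(keep)) + 200L),
      strength = 1)
    q_sites <- dplyr::bind_rows(base_sites[keep, ], novel)
    correlate_profiles(ref_prof, profile_for(q_sites), clade$chains$twin)$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.85)
  expect_lt(rs[1], 0.2)
})

test_that("degenerate correlation inputs raise errors", {
  set.seed(411)
  clade <- evolve_clade(20000, c(twin = 0))
  track <- mappability_track(clade$reference, 36)
  chip <- simulate_chip_reads(clade, binding_landscape(n_sites = 5),
                              n_reads = 1000, species = "reference")
  prof <- occupancy_pipeline(chip$reads$reference, track, L = 200L)
  empty_map <- chain_map(prof_blocks <- tibble::tibble(
    chain_id = integer(), score = numeric(), ref_chrom = character(),
    ref_start = integer(), ref_end = integer(), q_chrom = character(),
    q_start = integer(), q_end = integer(), q_strand = character()),
    c(chr1 = 20000L), c(chr1 = 20000L))
  expect_error(correlate_profiles(prof, prof, empty_map),
               class = "netdecay_empty_error")
  raw <- impute_density(chip$reads$reference, 200L, c(chr1 = 20000L))
  expect_error(correlate_profiles(raw, prof, clade$chains$twin),
               class = "netdecay_contract_error")
})
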