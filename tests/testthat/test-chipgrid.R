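bg_reads <- function(n, glen, chrom = "chr1", read_length = 36L) {
  s <- sample.int(glen - read_length, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = s, end = s + read_length, seq = "N",
                 score = 1000L, strand = sample(c("+", "-"), n, TRUE))
}

site_reads <- function(n, center, L = 200L, chrom = "chr1",
                       read_length = 36L) {
  fs <- center - L %/% 2L + as.integer(round(rnorm(n, 0, 10)))
  fe <- fs + L
  strand <- sample(c("+", "-"), n, TRUE)
  s <- ifelse(strand == "+", fs, fe - read_length)
  tibble::tibble(chrom = chrom, start = as.integer(s),
                 end = as.integer(s + read_length), seq = "N", score = 1000L,
                 strand = strand)
}

test_that("the pipeline grid enumerates exactly 108 combinations", {
  grid <- pipeline_choices()
  expect_equal(nrow(grid), 108L)
  expect_equal(length(unique(grid$pipeline)), 108L)
  expect_equal(nrow(unique(grid[, c("peak_caller", "quality", "min_match",
                                    "reference_subset", "overlap")])), 108L)
})

test_that("a strongly enriched site is called at both tiers", {
  set.seed(501)
  glen <- 50000L
  reads <- dplyr::bind_rows(bg_reads(2000, glen), site_reads(2000, 25000L))
  ctrl <- bg_reads(2000, glen)
  for (caller in c("M", "S")) {
    for (tier in c("lenient", "stringent")) {
      pk <- call_peaks_standin(reads, ctrl, c(chr1 = glen), tier = tier,
                               caller = caller)
      expect_gte(nrow(pk), 1L)
      hit <- any(pk$start <= 25000 & pk$end >= 25000)
      expect_true(hit)
    }
  }
})

test_that("stringent calls are nested within lenient calls", {
  set.seed(502)
  glen <- 60000L
  centers <- c(10000L, 25000L, 40000L, 52000L)
  reads <- dplyr::bind_rows(
    bg_reads(3000, glen),
    purrr::map_dfr(centers, function(cc) {
      site_reads(sample(c(60, 600), 1), cc)
    }))
  ctrl <- bg_reads(3000, glen)
  for (caller in c("M", "S")) {
    len <- call_peaks_standin(reads, ctrl, c(chr1 = glen), "lenient", caller)
    str <- call_peaks_standin(reads, ctrl, c(chr1 = glen), "stringent", caller)
    if (nrow(str) == 0L) next
    covered <- vapply(seq_len(nrow(str)), function(i) {
      any(len$start <= str$start[i] & len$end >= str$end[i])
    }, logical(1))
    expect_true(all(covered))
  }
})

test_that("uniform background yields false calls consistent with the threshold", {
  set.seed(503)
  glen <- 100000L
  n_called <- 0L
  for (i in 1:10) {
    reads <- bg_reads(5000, glen)
    ctrl <- bg_reads(5000, glen)
    pk <- call_peaks_standin(reads, ctrl, c(chr1 = glen), "lenient", "M")
    n_called <- n_called + nrow(pk)
  }
  # ~667 windows x 1e-5 x 10 runs expected false windows << 1 per run
  expect_lte(n_called, 3L)
})

test_that("empty control falls back to the global background rate", {
  set.seed(504)
  glen <- 50000L
  reads <- dplyr::bind_rows(bg_reads(2000, glen), site_reads(500, 30000L))
  pk <- call_peaks_standin(reads, NULL, c(chr1 = glen), "lenient", "M")
  expect_true(any(pk$start <= 30000 & pk$end >= 30000))
})

test_that("replicate combination follows the merge and intersect rules", {
  p1 <- tibble::tibble(chrom = "chr1", start = c(100L, 500L),
                       end = c(200L, 600L))
  p2 <- tibble::tibble(chrom = "chr1", start = c(150L, 900L),
                       end = c(250L, 950L))
  m <- combine_replicates(p1, p2, "merge")
  expect_equal(m$start, c(100L, 500L, 900L))
  expect_equal(m$end, c(250L, 600L, 950L))
  i <- combine_replicates(p1, p2, "intersect")
  expect_equal(nrow(i), 1L)
  expect_equal(c(i$start, i$end), c(100L, 250L))
  # identical replicates: merge == intersect == input
  mi <- combine_replicates(p1, p1, "intersect")
  expect_equal(mi$start, p1$start)
  # disjoint replicates: intersect empty
  expect_equal(nrow(combine_replicates(p1[1, ], p2[2, ], "intersect")), 0L)
})

test_that("randomized replicate intersection matches a brute-force check", {
  set.seed(505)
  for (rep in 1:10) {
    mk <- function(n) {
      s <- sort(sample.int(5000, n))
      tibble::tibble(chrom = "chr1", start = s, end = s + sample.int(80, n) + 10L)
    }
    p1 <- mk(15); p2 <- mk(12)
    i <- combine_replicates(p1, p2, "intersect")
    m <- combine_replicates(p1, p2, "merge")
    keep <- vapply(seq_len(nrow(m)), function(k) {
      any(p1$start < m$end[k] & p1$end > m$start[k]) &&
        any(p2$start < m$end[k] & p2$end > m$start[k])
    }, logical(1))
    expect_equal(i, m[keep, ])
  }
})

test_that("reference subsets obey S within P within A", {
  set.seed(506)
  peaks <- tibble::tibble(chrom = "chr1", start = seq(0L, 900L, 100L),
                          end = seq(50L, 950L, 100L))
  lift_ok <- list(sp1 = runif(10) < 0.7, sp2 = runif(10) < 0.7,
                  sp3 = runif(10) < 0.7)
  a <- select_reference_subset(peaks, lift_ok, "A")
  p <- select_reference_subset(peaks, lift_ok, "P", pair_species = "sp2")
  s <- select_reference_subset(peaks, lift_ok, "S")
  expect_equal(nrow(a), 10L)
  expect_true(all(paste(s$start) %in% paste(p$start) |
                    nrow(s) == 0L))
  expect_lte(nrow(s), nrow(p))
  expect_lte(nrow(p), nrow(a))
  # everything maps everywhere: A == P == S
  all_ok <- list(sp1 = rep(TRUE, 10), sp2 = rep(TRUE, 10))
  expect_equal(select_reference_subset(peaks, all_ok, "S"), peaks)
})

test_that("overlap fractions follow the lenient and reciprocal-50% rules", {
  proj <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  q30 <- tibble::tibble(chrom = "chr1", start = 170L, end = 270L)
  expect_equal(occupancy_overlap_fraction(proj, q30, "L"), 1.0)
  expect_equal(occupancy_overlap_fraction(proj, q30, "S"), 0.0)
  q60 <- tibble::tibble(chrom = "chr1", start = 140L, end = 240L)
  expect_equal(occupancy_overlap_fraction(proj, q60, "S"), 1.0)
  expect_equal(occupancy_overlap_fraction(proj, proj, "L"), 1.0)
  expect_equal(occupancy_overlap_fraction(proj, proj, "S"), 1.0)
  expect_error(occupancy_overlap_fraction(proj[0, ], q30, "L"),
               class = "netdecay_empty_error")
})

test_that("random overlap sets match a brute-force per-segment check", {
  set.seed(507)
  for (rep in 1:10) {
    mk <- function(n) {
      s <- sort(sample.int(4000, n))
      tibble::tibble(chrom = "chr1", start = s, end = s + sample.int(60, n) + 20L)
    }
    proj <- mk(20); q <- mk(15)
    for (mode in c("L", "S")) {
      got <- occupancy_overlap_fraction(proj, q, mode)
      manual <- mean(vapply(seq_len(nrow(proj)), function(i) {
        w <- pmin(proj$end[i], q$end) - pmax(proj$start[i], q$start)
        if (mode == "L") any(w >= 1)
        else any(w >= 0.5 * (proj$end[i] - proj$start[i]) &
                   w >= 0.5 * (q$end - q$start))
      }, logical(1)))
      expect_equal(got, manual)
    }
  }
})

make_grid_experiments <- function(seed = 508, times = c(12, 40, 80),
                                  glen = 60000L) {
  set.seed(seed)
  landscape <- binding_landscape(n_sites = 40, conservation_half_life = 40,
                                 fragment_size = 200)
  mk_exp <- function(lineage, gstf) {
    clade <- evolve_clade(glen, stats::setNames(times, paste0("sp", seq_along(times))),
                          params = evol_params(loss_rate = 0.004))
    chip <- simulate_chip_reads(clade, landscape, n_reads = 12000)
    species <- purrr::imap(clade$chains, function(chain, sp) {
      list(reads = list(chip$reads[[sp]]),
           control = bg_reads(4000, Biostrings::width(clade$descendants[[sp]])[1]),
           chain = chain,
           chrom_sizes = stats::setNames(
             Biostrings::width(clade$descendants[[sp]]), "chr1"),
           time_myr = clade$times[[sp]])
    })
    list(lineage = lineage, gstf = gstf,
         chrom_sizes = c(chr1 = glen),
         ref_reads = list(chip$reads$reference),
         ref_control = bg_reads(4000, glen),
         species = species)
  }
  list(mk_exp("mammal_like", "TF_A"), mk_exp("insect_like", "TF_B"))
}

test_that("the grid runner produces one similarity series per pipeline", {
  exps <- make_grid_experiments()
  sub <- pipeline_choices()[c(1, 30, 60, 104), ]
  res <- run_chip_grid(exps, choices = sub)
  expect_equal(nrow(res$similarities), 4 * 2 * 3)
  expect_equal(sort(unique(res$similarities$pipeline)), sort(sub$pipeline))
  expect_true(all(res$similarities$similarity >= 0 &
                    res$similarities$similarity <= 1, na.rm = TRUE))
  expect_equal(nrow(res$comparisons), 4L)
  expect_true(all(res$comparisons$verdict %in%
                    c("different", "indistinguishable", NA)))
})

test_that("stringent overlap never retains more than lenient overlap", {
  exps <- make_grid_experiments(seed = 509)
  ch <- pipeline_choices()
  sub <- ch[ch$peak_caller == "M" & ch$quality == "L" &
              ch$min_match == "N" & ch$reference_subset == "P", ]
  res <- run_chip_grid(exps, choices = sub)
  wide <- tidyr::pivot_wider(
    res$similarities[, c("pipeline", "experiment", "species", "similarity")],
    names_from = "pipeline", values_from = "similarity")
  l_col <- sub$pipeline[sub$overlap == "L"]
  s_col <- sub$pipeline[sub$overlap == "S"]
  expect_true(all(wide[[s_col]] <= wide[[l_col]] + 1e-12, na.rm = TRUE))
})

test_that("stricter min_match never lifts more segments", {
  set.seed(510)
  clade <- evolve_clade(50000, c(sp = 60),
                        params = evol_params(loss_rate = 0.006))
  segs <- sample_segments(tibble::tibble(chrom = "chr1", start = 0L,
                                         end = 50000L), 300, 75)
  n_lifted <- vapply(c(0.001, 0.5, 0.95), function(mm) {
    sum(lift_intervals(segs, clade$chains$sp, min_match = mm)$lifted)
  }, numeric(1))
  expect_true(all(diff(n_lifted) <= 0))
})

test_that("six GSTF pairs arise from a 2 x 3 cross-lineage design", {
  exps <- c(
    purrr::map(1:2, function(i) list(lineage = "insect_like",
                                     gstf = paste0("ITF", i))),
    purrr::map(1:3, function(i) list(lineage = "mammal_like",
                                     gstf = paste0("MTF", i))))
  meta <- purrr::map_dfr(seq_along(exps), function(ei) {
    tibble::tibble(experiment = ei, lineage = exps[[ei]]$lineage,
                   gstf = exps[[ei]]$gstf)
  })
  pairs <- tidyr::expand_grid(a = seq_len(nrow(meta)), b = seq_len(nrow(meta))) |>
    dplyr::filter(a < b, meta$lineage[a] != meta$lineage[b])
  expect_equal(nrow(pairs), 6L)
})
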