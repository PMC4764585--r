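#' Binding landscape for ChIP read simulation
#'
#' Describes the GSTF binding sites of a clade: site count and strengths on
#' the reference genome, the half-life (in Myrs) with which a site survives
#' along a branch, and the mean sequenced fragment size `L` used when placing
#' reads around a site. Sites lost along a branch are compensated by an equal
#' number of species-specific sites at random positions, so total occupancy is
#' stationary while the cross-species overlap decays as
#' \eqn{2^{-t/\tau_{1/2}}}.
#'
#' @param n_sites Number of binding sites on the reference genome.
#' @param conservation_half_life Site survival half-life in Myrs (default 30,
#'   which puts the cross-species profile correlation near 0.1 at 100 Myrs).
#' @param fragment_size Mean fragment size `L` in bp (default 200).
#' @param strength_meanlog,strength_sdlog Log-normal site strength parameters.
#' @return A `binding_landscape` list.
#' @export
binding_landscape <- function(n_sites = 200, conservation_half_life = 30,
                              fragment_size = 200,
                              strength_meanlog = 0, strength_sdlog = 0.5) {
  stopifnot(n_sites >= 0, conservation_half_life > 0, fragment_size >= 20)
  structure(list(n_sites = as.integer(n_sites),
                 conservation_half_life = conservation_half_life,
                 fragment_size = as.integer(fragment_size),
                 strength_meanlog = strength_meanlog,
                 strength_sdlog = strength_sdlog),
            class = "binding_landscape")
}

# reference sites + per-descendant site sets with exponential survival and
# compensating turnover
place_sites <- function(clade, landscape) {
  chrom <- names(clade$reference)[1L]
  L <- Biostrings::width(clade$reference)[1L]
  n <- landscape$n_sites
  ref_sites <- tibble::tibble(
    chrom = chrom,
    position = sort(sample.int(L - 200L, n) + 100L),
    strength = stats::rlnorm(n, landscape$strength_meanlog,
                             landscape$strength_sdlog)
  )
  per_species <- purrr::imap(clade$chains, function(chain, sp) {
    t <- clade$times[[sp]]
    surv <- stats::runif(n) < 2^(-t / landscape$conservation_half_life)
    mapped <- map_positions(chain, chrom, ref_sites$position[surv])
    keep <- !is.na(mapped$q_pos)
    qlen <- chain$q_sizes[[chrom]]
    n_new <- n - sum(keep)
    shared <- tibble::tibble(chrom = chrom,
                             position = mapped$q_pos[keep],
                             strength = ref_sites$strength[surv][keep],
                             shared = TRUE)
    novel <- tibble::tibble(chrom = chrom,
                            position = sample.int(max(qlen - 200L, 1L), n_new,
                                                  replace = TRUE) + 100L,
                            strength = stats::rlnorm(n_new,
                                                     landscape$strength_meanlog,
                                                     landscape$strength_sdlog),
                            shared = FALSE)
    dplyr::arrange(dplyr::bind_rows(shared, novel), .data$position)
  })
  list(reference = ref_sites, descendants = per_species)
}

#' Simulate ChIP read sets (tagAlign) over a synthetic clade
#'
#' Places binding sites on the reference genome, propagates them to each
#' descendant through the ground-truth chains with survival probability
#' \eqn{2^{-t/\tau_{1/2}}} (lost sites are replaced by species-specific
#' sites), and draws sequencing reads: fragments of length `L` centred on a
#' site with Gaussian jitter, read starts taken at fragment 5' ends on the
#' plus strand and fragment 3' ends on the minus strand, plus a uniform
#' background component. Per-site read counts are proportional to site
#' strength.
#'
#' @param clade A [evolve_clade()] result.
#' @param landscape A [binding_landscape()].
#' @param n_reads Reads per species (default 30000).
#' @param read_length Read length in bp (default 36).
#' @param background_frac Fraction of reads drawn uniformly (default 0.2).
#' @param jitter_sd Gaussian jitter of fragment centres around the site (bp).
#' @param species Which genomes to simulate; default the reference plus all
#'   descendants.
#' @return A list with `reads` (named list of tagAlign tibbles: `chrom`,
#'   `start`, `end`, `seq`, `score`, `strand`), `sites` (the per-species truth
#'   site tables) and `landscape`. Fragments running past a chromosome end
#'   are truncated and counted in `n_truncated` attributes.
#' @export
simulate_chip_reads <- function(clade, landscape = binding_landscape(),
                                n_reads = 30000, read_length = 36,
                                background_frac = 0.2, jitter_sd = 20,
                                species = NULL) {
  stopifnot(inherits(clade, "synthetic_clade"),
            inherits(landscape, "binding_landscape"))
  sites <- place_sites(clade, landscape)
  genomes <- c(list(reference = clade$reference), clade$descendants)
  site_tabs <- c(list(reference = dplyr::mutate(sites$reference, shared = TRUE)),
                 sites$descendants)
  if (is.null(species)) species <- names(genomes)
  reads <- purrr::map(species, function(sp) {
    simulate_reads_one(genomes[[sp]], site_tabs[[sp]], landscape,
                       n_reads = n_reads, read_length = read_length,
                       background_frac = background_frac, jitter_sd = jitter_sd)
  })
  names(reads) <- species
  list(reads = reads, sites = site_tabs, landscape = landscape)
}

simulate_reads_one <- function(genome, sites, landscape, n_reads, read_length,
                               background_frac, jitter_sd) {
  chrom <- names(genome)[1L]
  glen <- Biostrings::width(genome)[1L]
  L <- landscape$fragment_size
  n_bg <- round(n_reads * background_frac)
  n_sig <- n_reads - n_bg
  if (nrow(sites) == 0L) {
    n_bg <- n_reads; n_sig <- 0L
  }
  centers <- integer(0)
  if (n_sig > 0L) {
    pick <- sample.int(nrow(sites), n_sig, replace = TRUE, prob = sites$strength)
    centers <- sites$position[pick] +
      as.integer(round(stats::rnorm(n_sig, 0, jitter_sd)))
  }
  if (n_bg > 0L) {
    # background fragments uniform over the chromosome
    centers <- c(centers, sample.int(glen, n_bg, replace = TRUE) - 1L)
  }
  fs <- centers - L %/% 2L
  fe <- fs + L
  n_truncated <- sum(fs < 0L | fe > glen)
  fs <- pmax.int(fs, 0L)
  fe <- pmin.int(fe, glen)
  ok <- fe - fs >= read_length
  fs <- fs[ok]; fe <- fe[ok]
  strand <- sample(c("+", "-"), length(fs), replace = TRUE)
  start <- ifelse(strand == "+", fs, fe - read_length)
  out <- tibble::tibble(chrom = chrom, start = as.integer(start),
                        end = as.integer(start + read_length),
                        seq = "N", score = 1000L, strand = strand)
  attr(out, "n_truncated") <- n_truncated
  attr(out, "read_length") <- as.integer(read_length)
  out
}

#' Write/read tagAlign files
#'
#' tagAlign is the minimal BED-like read interchange format: chrom, start,
#' end, sequence (or `N`), score, strand.
#'
#' @param reads A tagAlign tibble.
#' @param path File path.
#' @return `read_tagalign` returns a tibble; `write_tagalign` returns `path`
#'   invisibly.
#' @export
write_tagalign <- function(reads, path) {
  readr::write_tsv(reads[, c("chrom", "start", "end", "seq", "score", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_tagalign
#' @export
read_tagalign <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "seq", "score", "strand"),
                  col_types = "ciicic", progress = FALSE)
}
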