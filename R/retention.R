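#' Sample fixed-length segments uniformly without overlap
#'
#' Rejection-samples `n` segments of length `len` uniformly within the given
#' regions so that no two segments overlap (the in-code equivalent of
#' shuffling segment locations with a no-overlap constraint).
#'
#' @param regions Tibble `chrom`, `start`, `end` delineating allowed space.
#' @param n Number of segments.
#' @param len Segment length in bp.
#' @return Tibble `chrom`, `start`, `end` of `n` non-overlapping segments.
#' @export
sample_segments <- function(regions, n, len) {
  regions <- regions[regions$end - regions$start >= len, , drop = FALSE]
  space <- sum(regions$end - regions$start)
  if (space < n * len) {
    stop_netdecay("not enough region space for requested segments")
  }
  starts_per_region <- regions$end - regions$start - len + 1L
  cum <- cumsum(starts_per_region)
  total <- cum[length(cum)]
  picked_chrom <- character(n)
  picked_start <- integer(n)
  occupied <- list()
  n_placed <- 0L
  attempts <- 0L
  while (n_placed < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n) {
      stop_netdecay("could not place non-overlapping segments")
    }
    u <- sample.int(total, 1L)
    ri <- findInterval(u - 1L, c(0L, cum), rightmost.closed = FALSE)
    off <- u - c(0L, cum)[ri] - 1L
    chrom <- regions$chrom[ri]
    s <- regions$start[ri] + off
    occ <- occupied[[chrom]]
    if (!is.null(occ) && any(s < occ[, 2L] & s + len > occ[, 1L])) next
    occupied[[chrom]] <- rbind(occ, c(s, s + len))
    n_placed <- n_placed + 1L
    picked_chrom[n_placed] <- chrom
    picked_start[n_placed] <- s
  }
  tibble::tibble(chrom = picked_chrom, start = picked_start,
                 end = picked_start + len)
}

#' Segment-retention sampling: fraction of random segments keeping homology
#'
#' Repeatedly samples `n_segments` non-overlapping segments of
#' `segment_length` bp within `regions`, lifts them through the chain map
#' (minMatch `min_match`, excluding segments that map to a region longer than
#' `max_target_span`), and records the fraction that lift successfully. The
#' trial-mean fraction is the cross-species similarity measure used for the
#' genome-sequence layer.
#'
#' @param regions Allowed sampling space (tibble `chrom`, `start`, `end`),
#'   e.g. the whole genome, or accessible/inaccessible intergenic space.
#' @param map A [chain_map()].
#' @param n_segments Segments per trial (default 5000).
#' @param segment_length Segment length in bp (default 75).
#' @param n_trials Number of independent trials (default 20).
#' @param min_match LiftOver minMatch (default 0.001).
#' @param max_target_span Maximum query span (default 1000 bp).
#' @return An object of class `retention_result`: list with
#'   `fraction_retained` (mean over trials), `per_trial` tibble, and the
#'   sampling parameters.
#' @export
sample_retention <- function(regions, map, n_segments = 5000,
                             segment_length = 75, n_trials = 20,
                             min_match = 0.001, max_target_span = 1000) {
  per_trial <- numeric(n_trials)
  for (trial in seq_len(n_trials)) {
    segs <- sample_segments(regions, n_segments, segment_length)
    lifted <- lift_intervals(segs, map, min_match = min_match,
                             max_target_span = max_target_span)
    per_trial[trial] <- mean(lifted$lifted)
  }
  structure(list(fraction_retained = mean(per_trial),
                 per_trial = tibble::tibble(trial = seq_len(n_trials),
                                            fraction = per_trial),
                 n_segments = n_segments, segment_length = segment_length,
                 n_trials = n_trials, min_match = min_match,
                 max_target_span = max_target_span),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf(
    "<retention_result> %.1f%% retained (%d x %d bp segments, %d trials)\n",
    100 * x$fraction_retained, x$n_segments, x$segment_length, x$n_trials))
  invisible(x)
}

#' @rdname sample_retention
#' @param x A `retention_result`.
#' @param ... Unused.
#' @export
tidy.retention_result <- function(x, ...) x$per_trial

#' @rdname sample_retention
#' @export
glance.retention_result <- function(x, ...) {
  tibble::tibble(fraction_retained = x$fraction_retained,
                 sd = stats::sd(x$per_trial$fraction),
                 n_segments = x$n_segments,
                 segment_length = x$segment_length, n_trials = x$n_trials)
}

#' The EDNAFULL (NUC.4.4) nucleotide scoring matrix
#'
#' Match +5 / mismatch -4 for unambiguous bases, with the published scores
#' for IUPAC ambiguity codes.
#'
#' @return A 15 x 15 numeric matrix.
#' @export
ednafull_matrix <- function() {
  letters15 <- c("A", "T", "G", "C", "S", "W", "R", "Y", "K", "M",
                 "B", "V", "H", "D", "N")
  m <- matrix(c(
     5, -4, -4, -4, -4,  1,  1, -4, -4,  1, -4, -1, -1, -1, -2,
    -4,  5, -4, -4, -4,  1, -4,  1,  1, -4, -1, -4, -1, -1, -2,
    -4, -4,  5, -4,  1, -4,  1, -4,  1, -4, -1, -1, -4, -1, -2,
    -4, -4, -4,  5,  1, -4, -4,  1, -4,  1, -1, -1, -1, -4, -2,
    -4, -4,  1,  1, -1, -4, -2, -2, -2, -2, -1, -1, -3, -3, -1,
     1,  1, -4, -4, -4, -1, -2, -2, -2, -2, -3, -3, -1, -1, -1,
     1, -4,  1, -4, -2, -2, -1, -4, -2, -2, -3, -1, -3, -1, -1,
    -4,  1, -4,  1, -2, -2, -4, -1, -2, -2, -1, -3, -1, -3, -1,
    -4,  1,  1, -4, -2, -2, -2, -2, -1, -4, -1, -3, -3, -1, -1,
     1, -4, -4,  1, -2, -2, -2, -2, -4, -1, -3, -1, -1, -3, -1,
    -4, -1, -1, -1, -1, -3, -3, -1, -1, -3, -1, -2, -2, -2, -1,
    -1, -4, -1, -1, -1, -3, -1, -3, -3, -1, -2, -1, -2, -2, -1,
    -1, -1, -4, -1, -3, -1, -3, -1, -3, -1, -2, -2, -1, -2, -1,
    -1, -1, -1, -4, -3, -1, -1, -3, -1, -3, -2, -2, -2, -1, -1,
    -2, -2, -2, -2, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1
  ), nrow = 15, byrow = TRUE, dimnames = list(letters15, letters15))
  m
}

#' Local-alignment percent identity of lifted segments
#'
#' Aligns each successfully lifted segment against its query image with
#' Smith-Waterman local alignment (EDNAFULL scores, affine gaps: opening 10,
#' extension 0.5) and reports identity as matches over aligned non-gap
#' columns -- the identity of the ungapped alignment columns. Segments whose
#' best local alignment is empty (score 0) are excluded and counted.
#'
#' @param lifted Output of [lift_intervals()] (rows with `lifted == TRUE` are
#'   used).
#' @param ref_genome,query_genome `DNAStringSet`s.
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 0.5).
#' @return A list with `mean_identity` (percent), `per_segment` tibble and
#'   `n_excluded`.
#' @export
ungapped_identity <- function(lifted, ref_genome, query_genome,
                              gap_open = 10, gap_extend = 0.5) {
  seg <- lifted[lifted$lifted, , drop = FALSE]
  if (nrow(seg) == 0L) {
    stop_netdecay("no lifted segments", class = "netdecay_empty_error")
  }
  mat <- ednafull_matrix()
  ident <- rep(NA_real_, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    rseq <- Biostrings::subseq(ref_genome[[seg$chrom[i]]],
                               seg$start[i] + 1L, seg$end[i])
    qseq <- Biostrings::subseq(query_genome[[seg$q_chrom[i]]],
                               seg$q_start[i] + 1L, seg$q_end[i])
    if (identical(seg$q_strand[i], "-")) {
      qseq <- Biostrings::reverseComplement(qseq)
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rseq), Biostrings::DNAString(qseq),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    if (Biostrings::score(al) <= 0) next
    nm <- Biostrings::nmatch(al)
    nmm <- Biostrings::nmismatch(al)
    if (nm + nmm == 0L) next
    ident[i] <- 100 * nm / (nm + nmm)
  }
  ok <- !is.na(ident)
  list(mean_identity = mean(ident[ok]),
       per_segment = tibble::tibble(chrom = seg$chrom, start = seg$start,
                                    end = seg$end, identity = ident),
       n_excluded = sum(!ok))
}
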