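#' Position weight matrices: construction and I/O
#'
#' A PWM here is a 4 x w matrix of per-position log2-odds scores over
#' `A, C, G, T` against a 0-order background, built from a count (or
#' frequency) matrix with a pseudocount of 0.1 per cell, as FIMO does by
#' default. [read_jaspar()] parses the JASPAR pfm text format; [read_meme()]
#' parses the MEME minimal motif format (letter-probability matrix).
#'
#' @param counts A 4 x w numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param background Length-4 background probabilities (default uniform);
#'   typically the reference genome base composition.
#' @param pseudocount Pseudocount added per cell (default 0.1).
#' @param name Motif name.
#' @return An object of class `pwm`: the log2-odds score matrix with
#'   attributes `name`, `background` and `probs`.
#' @export
pwm_from_counts <- function(counts, background = rep(0.25, 4),
                            pseudocount = 0.1, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_netdecay("count matrix must have 4 rows (A, C, G, T)")
  stopifnot(all(counts >= 0), length(background) == 4L,
            all(background > 0), abs(sum(background) - 1) < 1e-6)
  probs <- sweep(counts + pseudocount, 2L,
                 colSums(counts) + 4 * pseudocount, "/")
  scores <- log2(probs / background)
  rownames(scores) <- rownames(probs) <- c("A", "C", "G", "T")
  structure(scores, name = name, background = background, probs = probs,
            class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, consensus %s\n", attr(x, "name"),
              ncol(x), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per column)
#' @param pwm A `pwm`.
#' @return A character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(attr(pwm, "probs"), 2L, which.max)],
        collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm A `pwm`.
#' @return A `pwm` scoring the minus strand.
#' @export
pwm_revcomp <- function(pwm) {
  m <- unclass(pwm)[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  p <- attr(pwm, "probs")[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(p) <- c("A", "C", "G", "T")
  structure(m, name = attr(pwm, "name"), background = attr(pwm, "background"),
            probs = p, class = c("pwm", "matrix"))
}

#' @rdname pwm_from_counts
#' @param path Path to a JASPAR pfm (or MEME minimal) motif file.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- sub("^>\\s*", "", lines[grepl("^>", lines)][1L])
  if (is.na(name)) name <- "motif"
  rows <- grep("^[ACGT]\\s*\\[", lines, value = TRUE)
  if (length(rows) != 4L) {
    # headerless 4-line numeric variant
    rows <- grep("^[0-9eE. \t+-]+$", lines, value = TRUE)
  }
  if (length(rows) < 4L) stop_netdecay("could not parse JASPAR matrix")
  parse_row <- function(r) {
    nums <- regmatches(r, gregexpr("[0-9.eE+-]+", r))[[1L]]
    as.numeric(nums)
  }
  mat <- do.call(rbind, lapply(rows[1:4], parse_row))
  # rows are in A C G T order in both variants
  pwm_from_counts(mat, background = background, pseudocount = pseudocount,
                  name = name)
}

#' @rdname pwm_from_counts
#' @export
read_meme <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- readLines(path)
  mi <- grep("^MOTIF\\b", lines)
  if (length(mi) == 0L) stop_netdecay("no MOTIF record found")
  name <- strsplit(trimws(lines[mi[1L]]), "\\s+")[[1L]][2L]
  hi <- grep("letter-probability matrix", lines)
  hi <- hi[hi > mi[1L]][1L]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
  rows <- lines[(hi + 1L):(hi + w)]
  mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x)[1:4], numeric(4)))
  # probability rows scale to pseudocounted probabilities directly
  pwm_from_counts(t(mat) * 100, background = background,
                  pseudocount = pseudocount, name = name)
}

#' Exact PWM score threshold for a match p-value
#'
#' Computes the exact null distribution of PWM scores for random sequence
#' drawn from the 0-order background, by dynamic programming over motif
#' positions on a discretized score lattice, and returns the smallest score
#' whose upper-tail probability is strictly below `alpha`. This reproduces
#' FIMO-style p-value thresholding (default `alpha = 1e-4`).
#'
#' @param pwm A `pwm` (length at most 30 for the exact DP).
#' @param alpha Match p-value in (0, 1).
#' @param granularity Score discretization step in log2-odds units (default
#'   1e-4).
#' @return A list with `cutoff` (score threshold), `p_at_cutoff` and `alpha`.
#' @export
pwm_pvalue_threshold <- function(pwm, alpha = 1e-4, granularity = 1e-4) {
  stopifnot(inherits(pwm, "pwm"))
  if (alpha <= 0 || alpha > 1) stop_netdecay("alpha must be in (0, 1]")
  w <- ncol(pwm)
  if (w > 30L) stop_netdecay("exact DP supports motif length <= 30")
  bg <- attr(pwm, "background")
  if (alpha == 1) {
    # everything passes, including the all-worst-base word
    return(list(cutoff = sum(apply(unclass(pwm), 2L, min)), p_at_cutoff = 1,
                alpha = alpha))
  }
  s_int <- round(unclass(pwm) / granularity)
  lo <- sum(apply(s_int, 2L, min))
  hi <- sum(apply(s_int, 2L, max))
  # dense probability vector over the achievable integer score range
  dist <- numeric(hi - lo + 1L)
  # start before any position: single mass at score 0, tracked via offset
  cur <- 1
  cur_lo <- 0L
  for (j in seq_len(w)) {
    col <- s_int[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1L + max(col)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  scores <- (cur_lo + seq_along(cur) - 1L) * granularity
  tail_p <- rev(cumsum(rev(cur)))
  # restrict to achievable scores (nonzero mass) so the cutoff is a real
  # word score rather than an empty lattice point inside a gap
  ok <- tail_p < alpha & cur > 0
  if (!any(ok)) {
    # nothing passes: threshold just above the maximum achievable score
    return(list(cutoff = max(scores) + granularity, p_at_cutoff = 0,
                alpha = alpha))
  }
  i <- which(ok)[1L]
  # scores[i] is the smallest achievable lattice score with tail < alpha;
  # subtract half the worst-case rounding (w * granularity / 2) so the
  # boundary word, whose exact score may round up, is still admitted
  list(cutoff = scores[i] - 0.5 * granularity * w,
       p_at_cutoff = tail_p[i], alpha = alpha)
}

# integer-coded chromosome sequence (A=1 C=2 G=3 T=4, else NA)
encode_seq <- function(seq_chr) {
  match(strsplit(seq_chr, "")[[1L]], c("A", "C", "G", "T"))
}

scan_strand <- function(codes, mat, cutoff) {
  w <- ncol(mat)
  n <- length(codes)
  if (n < w) return(integer(0))
  np <- n - w + 1L
  sc <- numeric(np)
  valid <- !logical(np)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + np - 1L)]
    bad <- is.na(cj)
    if (any(bad)) {
      valid <- valid & !bad
      cj[bad] <- 1L
    }
    sc <- sc + mat[cbind(cj, j)]
  }
  which(valid & sc >= cutoff)
}

#' Scan a genome for PWM matches above a score cutoff
#'
#' Scores every position of every chromosome on both strands and reports
#' matches at or above `cutoff` (typically from [pwm_pvalue_threshold()]).
#'
#' @param genome A `DNAStringSet`.
#' @param pwm A `pwm`.
#' @param cutoff Score threshold.
#' @return A BED-like tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `score`.
#' @export
scan_genome <- function(genome, pwm, cutoff) {
  stopifnot(inherits(pwm, "pwm"))
  if (sum(Biostrings::width(genome)) == 0L) stop_netdecay("empty genome")
  w <- ncol(pwm)
  mat_f <- unclass(pwm)
  mat_r <- unclass(pwm_revcomp(pwm))
  out <- purrr::imap_dfr(as.list(as.character(genome)), function(seq_chr, chrom) {
    codes <- encode_seq(seq_chr)
    hit_f <- scan_strand(codes, mat_f, cutoff)
    hit_r <- scan_strand(codes, mat_r, cutoff)
    dplyr::bind_rows(
      tibble::tibble(chrom = chrom, start = hit_f - 1L, end = hit_f - 1L + w,
                     strand = "+"),
      tibble::tibble(chrom = chrom, start = hit_r - 1L, end = hit_r - 1L + w,
                     strand = "-")
    )
  })
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

#' Motif retention statistic F between two genomes
#'
#' Lifts the reference-genome motif matches to the query genome through a
#' chain map (minMatch 0.001), extends each lifted segment by `extension` bp
#' (both directions by default), and counts segments containing at least one
#' significant query match (`mapped_with_motif`). Background expectation is
#' estimated by placing the same number of equally-sized segments uniformly at
#' random on the query chromosomes and re-counting
#' (`shuffled_mapped_with_motif`). The retention statistic is
#' \deqn{F = \frac{\mathit{mapped\_with\_motif} -
#'   \mathit{shuffled\_mapped\_with\_motif}}{\mathit{mapped}} \times 100.}
#'
#' @param matches Reference matches from [scan_genome()].
#' @param map A [chain_map()] from reference to query.
#' @param query_genome Query `DNAStringSet`.
#' @param pwm,cutoff Motif and score threshold used for the query scan.
#' @param extension Extension in bp (default 50).
#' @param two_sided Extend both directions (default) or only 3'-ward.
#' @return An object of class `motif_retention`: list with counts `mapped`,
#'   `mapped_with_motif`, `shuffled_mapped_with_motif` and the statistic `F`
#'   (percent).
#' @export
motif_retention <- function(matches, map, query_genome, pwm, cutoff,
                            extension = 50, two_sided = TRUE) {
  if (nrow(matches) == 0L) {
    stop_netdecay("no reference matches; F undefined",
                  class = "netdecay_empty_error")
  }
  lifted <- lift_intervals(matches[, c("chrom", "start", "end")], map,
                           min_match = 0.001, max_target_span = 1000)
  lifted <- lifted[lifted$lifted, , drop = FALSE]
  mapped <- nrow(lifted)
  if (mapped == 0L) {
    stop_netdecay("no matches lifted; F undefined",
                  class = "netdecay_empty_error")
  }
  q_sizes <- stats::setNames(Biostrings::width(query_genome),
                             names(query_genome))
  ext_s <- lifted$q_start - if (two_sided) extension else 0L
  ext_e <- lifted$q_end + extension
  seg <- tibble::tibble(chrom = lifted$q_chrom,
                        start = pmax.int(ext_s, 0L),
                        end = pmin.int(ext_e, q_sizes[lifted$q_chrom]))
  q_matches <- scan_genome(query_genome, pwm, cutoff)
  mwm <- count_segments_with_match(seg, q_matches)
  # shuffled background: same segment lengths, uniform placement per chromosome
  lens <- seg$end - seg$start
  shuf <- tibble::tibble(
    chrom = seg$chrom,
    start = vapply(seq_along(lens), function(i) {
      sample.int(max(q_sizes[[seg$chrom[i]]] - lens[i], 1L), 1L) - 1L
    }, integer(1))
  )
  shuf$end <- shuf$start + lens
  smwm <- count_segments_with_match(shuf, q_matches)
  structure(list(mapped = mapped, mapped_with_motif = mwm,
                 shuffled_mapped_with_motif = smwm,
                 F = (mwm - smwm) / mapped * 100,
                 extension = extension, two_sided = two_sided),
            class = "motif_retention")
}

# number of segments containing >= 1 full match
count_segments_with_match <- function(segments, matches) {
  if (nrow(segments) == 0L) return(0L)
  if (nrow(matches) == 0L) return(0L)
  n_with <- 0L
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    m <- matches[matches$chrom == chrom, , drop = FALSE]
    if (nrow(m) == 0L) next
    # a match counts only if fully inside the segment
    hits <- IRanges::findOverlaps(IRanges::IRanges(m$start + 1L, m$end),
                                  IRanges::IRanges(s$start + 1L, s$end),
                                  type = "within")
    n_with <- n_with + length(unique(S4Vectors::subjectHits(hits)))
  }
  n_with
}

#' @export
print.motif_retention <- function(x, ...) {
  cat(sprintf("<motif_retention> mapped %d, with motif %d, shuffled %d, F = %.1f%%\n",
              x$mapped, x$mapped_with_motif, x$shuffled_mapped_with_motif, x$F))
  invisible(x)
}

#' @rdname motif_retention
#' @param x A `motif_retention`.
#' @param ... Unused.
#' @export
tidy.motif_retention <- function(x, ...) {
  tibble::tibble(mapped = x$mapped, mapped_with_motif = x$mapped_with_motif,
                 shuffled_mapped_with_motif = x$shuffled_mapped_with_motif,
                 F = x$F)
}
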