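#' Per-strand 5' read start-site densities
#'
#' Counts read 5' start sites per genomic position, separately per strand.
#' For plus-strand reads the 5' start is the leftmost base (`start`); for
#' minus-strand reads it is the rightmost base (`end - 1` in 0-based
#' half-open coordinates). Only start sites enter the cross-correlation
#' fragment-size estimator, not whole-read coverage.
#'
#' @param reads A tagAlign tibble (`chrom`, `start`, `end`, `strand`).
#' @param chrom_sizes Named integer vector of chromosome sizes.
#' @return An object of class `start_density`: list with per-chromosome
#'   integer vectors `plus` and `minus` (index 1 = position 0).
#' @export
start_site_density <- function(reads, chrom_sizes) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  dens <- purrr::imap(as.list(chrom_sizes), function(n, chrom) {
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    plus5 <- r$start[r$strand == "+"]
    minus5 <- r$end[r$strand == "-"] - 1L
    list(plus = tabulate(plus5 + 1L, nbins = n),
         minus = tabulate(minus5 + 1L, nbins = n))
  })
  structure(list(density = dens, chrom_sizes = chrom_sizes),
            class = "start_density")
}

#' Remove presumed PCR duplicates
#'
#' Reads sharing the same (chromosome, strand, 5' start site) are presumed
#' PCR duplicates; one representative is kept.
#'
#' @param reads A tagAlign tibble.
#' @return The deduplicated tibble.
#' @export
dedup_reads <- function(reads) {
  start5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  reads[!duplicated(data.frame(reads$chrom, reads$strand, start5)), ,
        drop = FALSE]
}

#' Estimate the mean fragment size by strand cross-correlation
#'
#' For each candidate offset `k`, computes the Pearson correlation between
#' the plus-strand start-site density and the minus-strand density shifted
#' left by `k` (pooled over chromosomes). The first peak of the
#' cross-correlation curve is located by taking the finite-difference first
#' derivative, smoothing it with a Gaussian kernel (standard deviation
#' `bandwidth` offsets, truncated at 4 sigma), and finding the first downward
#' zero-crossing; that offset is the estimated mean fragment size `L`.
#'
#' The search starts at `read_length + 1` by default, past the phantom peak
#' that read-length-scale correlation produces.
#'
#' @param starts A [start_site_density()].
#' @param max_offset Largest offset searched (default 600 bp).
#' @param min_offset Smallest offset searched; defaults to `read_length + 1`.
#' @param read_length Read length in bp (used for the default `min_offset`).
#' @param bandwidth Gaussian smoothing bandwidth in offsets (default 10).
#' @return An object of class `fragment_size_estimate`: list with `L`, the
#'   `curve` tibble (`offset`, `r`, `dr`, `dr_smooth`), and the search
#'   settings.
#' @export
estimate_fragment_size <- function(starts, max_offset = 600,
                                   min_offset = NULL, read_length = 36,
                                   bandwidth = 10) {
  stopifnot(inherits(starts, "start_density"))
  if (is.null(min_offset)) min_offset <- read_length + 1L
  offsets <- seq.int(min_offset, max_offset)
  if (length(offsets) < 5L) stop_netdecay("offset range too narrow")
  plus_all <- lapply(starts$density, `[[`, "plus")
  minus_all <- lapply(starts$density, `[[`, "minus")
  if (sum(unlist(plus_all)) == 0L || sum(unlist(minus_all)) == 0L) {
    stop_netdecay("both strands must carry reads",
                  class = "netdecay_empty_error")
  }
  r <- vapply(offsets, function(k) {
    xs <- ys <- list()
    for (i in seq_along(plus_all)) {
      n <- length(plus_all[[i]])
      if (n <= k + 1L) next
      xs[[length(xs) + 1L]] <- plus_all[[i]][1:(n - k)]
      ys[[length(ys) + 1L]] <- minus_all[[i]][(k + 1L):n]
    }
    x <- unlist(xs); y <- unlist(ys)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop_netdecay("constant start-site density; correlation undefined")
    }
    stats::cor(x, y)
  }, numeric(1))
  dr <- c(diff(r), NA_real_)
  half <- 4L * bandwidth
  kern <- stats::dnorm(seq.int(-half, half), sd = bandwidth)
  dv <- dr[seq_len(length(dr) - 1L)]
  # Gaussian smoothing with edge renormalisation (clipped kernel at the ends)
  sm <- vapply(seq_along(dv), function(i) {
    lo <- max(1L, i - half); hi <- min(length(dv), i + half)
    kk <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
    sum(dv[lo:hi] * kk) / sum(kk)
  }, numeric(1))
  dr_smooth <- rep(NA_real_, length(dr))
  dr_smooth[seq_along(sm)] <- sm
  # the peak is the first downward zero-crossing after the smoothed
  # derivative has meaningfully risen; the threshold guards against sign
  # flips in the flat noise floor before the true peak
  if (!any(sm > 0)) {
    stop_netdecay(
      "cross-correlation never rises in the searched offset range; increase max_offset",
      class = "netdecay_estimation_error")
  }
  rise_thr <- 0.05 * max(sm)
  risen <- cumsum(sm >= rise_thr) > 0
  cross <- which(sm < 0 & c(FALSE, risen[-length(risen)]))
  if (length(cross) == 0L) {
    stop_netdecay(
      "no downward zero-crossing in the searched offset range; increase max_offset",
      class = "netdecay_estimation_error")
  }
  L <- offsets[cross[1L]]
  structure(list(L = as.integer(L),
                 curve = tibble::tibble(offset = offsets, r = r, dr = dr,
                                        dr_smooth = dr_smooth),
                 bandwidth = bandwidth, min_offset = min_offset,
                 max_offset = max_offset),
            class = "fragment_size_estimate")
}

#' @export
print.fragment_size_estimate <- function(x, ...) {
  cat(sprintf("<fragment_size_estimate> L = %d bp (offsets %d..%d, bandwidth %g)\n",
              x$L, x$min_offset, x$max_offset, x$bandwidth))
  invisible(x)
}

#' Plot a strand cross-correlation curve
#' @param object A `fragment_size_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fragment_size_estimate <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$offset, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$L, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Strand offset (bp)", y = "Pearson r",
                  subtitle = sprintf("estimated fragment size L = %d bp", object$L)) +
    ggplot2::theme_minimal()
}

#' Imputed fragment density from read start sites
#'
#' Extends each read's 5' start site by `L` bp in the 3' direction (rightward
#' for plus-strand reads, leftward from the 3'-end start site for minus-strand
#' reads) and accumulates per-position fragment counts, separately per strand.
#' Fragments running past a chromosome boundary are truncated and counted.
#'
#' @param reads tagAlign tibble.
#' @param L Imputed fragment length in bp (>= 1), typically from
#'   [estimate_fragment_size()].
#' @param chrom_sizes Named integer vector.
#' @return An object of class `occupancy_profile` with per-chromosome
#'   per-strand density vectors (`$density[[chrom]]$plus/minus`), `L`,
#'   and `n_truncated`; not yet mappability-normalized (`normalized = FALSE`).
#' @export
impute_density <- function(reads, L, chrom_sizes) {
  stopifnot(L >= 1)
  L <- as.integer(L)
  n_trunc <- 0L
  dens <- purrr::imap(as.list(chrom_sizes), function(n, chrom) {
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    acc <- function(from, to) {
      # accumulate +1 over [from, to) via difference vector
      tab_s <- tabulate(from + 1L, nbins = n)
      tab_e <- tabulate(to + 1L, nbins = n + 1L)
      cumsum(tab_s - tab_e[seq_len(n)])
    }
    p5 <- r$start[r$strand == "+"]
    m5 <- r$end[r$strand == "-"]          # exclusive end = 5' start + 1
    pf <- p5; pt <- pmin.int(p5 + L, n)
    mf <- pmax.int(m5 - L, 0L); mt <- m5
    n_trunc <<- n_trunc + sum(p5 + L > n) + sum(m5 - L < 0L)
    list(plus = acc(pf, pt), minus = acc(mf, mt))
  })
  structure(list(density = dens, chrom_sizes = chrom_sizes, L = L,
                 normalized = FALSE, mask = NULL, n_truncated = n_trunc),
            class = "occupancy_profile")
}

#' Merge replicate occupancy profiles by adding density vectors
#'
#' @param ... Unnormalized `occupancy_profile`s on the same genome and `L`.
#' @return A merged `occupancy_profile`.
#' @export
merge_profiles <- function(...) {
  ps <- list(...)
  stopifnot(length(ps) >= 1L, all(vapply(ps, inherits, logical(1),
                                         "occupancy_profile")))
  if (any(vapply(ps, function(p) isTRUE(p$normalized), logical(1)))) {
    stop_netdecay("replicates are merged before normalization",
                  class = "netdecay_contract_error")
  }
  if (length(unique(vapply(ps, `[[`, integer(1), "L"))) != 1L) {
    stop_netdecay("profiles have different L", class = "netdecay_contract_error")
  }
  out <- ps[[1L]]
  for (p in ps[-1L]) {
    for (chrom in names(out$density)) {
      out$density[[chrom]]$plus <- out$density[[chrom]]$plus + p$density[[chrom]]$plus
      out$density[[chrom]]$minus <- out$density[[chrom]]$minus + p$density[[chrom]]$minus
    }
  }
  out$n_truncated <- sum(vapply(ps, `[[`, integer(1), "n_truncated"))
  out
}

#' Uniquely-mappable read start positions of a genome
#'
#' Marks every position whose read of `read_length` bp occurs exactly once in
#' the two-stranded genome: exact k-mer counting over the forward sequences of
#' all chromosomes plus their reverse complements, equivalent to error-free
#' alignment with zero mismatches and removal of multi-mappers. The
#' minus-strand track marks 5' start sites of minus-strand reads (a position
#' `p` is minus-mappable iff the k-mer ending at `p` is unique).
#'
#' @param genome A `DNAStringSet`.
#' @param read_length Read length `k` in bp.
#' @return An object of class `mappability_track`: per-chromosome logical
#'   vectors `plus` and `minus`, plus `read_length`.
#' @export
mappability_track <- function(genome, read_length) {
  k <- as.integer(read_length)
  stopifnot(k >= 1L)
  sizes <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(k > sizes)) stop_netdecay("read_length exceeds a chromosome length")
  fwd <- lapply(as.character(genome), function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  })
  rcs <- as.character(Biostrings::reverseComplement(genome))
  rev_kmers <- lapply(rcs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  })
  all_fwd <- unlist(fwd, use.names = FALSE)
  # occurrences in the two-stranded genome: count(w) + count(revcomp(w))
  counts <- table(factor(all_fwd))
  lookup <- function(w) {
    out <- counts[w]
    out[is.na(out)] <- 0L
    as.integer(out)
  }
  track <- purrr::imap(fwd, function(kmers, chrom) {
    n <- sizes[[chrom]]
    rc_aligned <- rev(rev_kmers[[chrom]])   # revcomp of the k-mer at each position
    total <- lookup(kmers) + lookup(rc_aligned)
    uniq <- total == 1L
    plus <- logical(n)
    plus[seq_along(uniq)] <- uniq
    minus <- logical(n)
    minus[(k:n)] <- uniq                    # k-mer ending at p starts at p-k+1
    list(plus = plus, minus = minus)
  })
  structure(list(track = track, read_length = k,
                 chrom_sizes = stats::setNames(sizes, names(genome))),
            class = "mappability_track")
}

# windowed count of TRUE values in [p - L + 1, p] (upstream window incl. p)
window_count_left <- function(x, L) {
  cs <- cumsum(as.integer(x))
  n <- length(x)
  lo <- pmax.int(seq_len(n) - L, 0L)
  cs - c(0, cs)[lo + 1L]
}

#' Mappability-normalize an occupancy profile
#'
#' Divides the imputed fragment density at each position by the fraction of
#' positions within `L` bp upstream (strand-appropriate direction) that are
#' uniquely-mappable read start sites, and masks positions whose upstream
#' window contains no mappable start at all. Plus and minus strands are
#' normalized separately and then summed (set `pre_sum = TRUE` to sum before
#' normalizing with the combined window count instead).
#'
#' @param profile An unnormalized [impute_density()] profile.
#' @param track A [mappability_track()] on the same genome, with the same
#'   read length as the reads.
#' @param pre_sum Sum strands before normalization (default `FALSE`).
#' @return A normalized `occupancy_profile`: per-chromosome single `density`
#'   vector, logical `mask` (`TRUE` = excluded), `normalized = TRUE`.
#' @export
normalize_density <- function(profile, track, pre_sum = FALSE) {
  stopifnot(inherits(profile, "occupancy_profile"),
            inherits(track, "mappability_track"))
  if (isTRUE(profile$normalized)) {
    stop_netdecay("profile already normalized", class = "netdecay_contract_error")
  }
  if (!identical(sort(names(profile$density)), sort(names(track$track)))) {
    stop_netdecay("profile and track cover different chromosomes",
                  class = "netdecay_contract_error")
  }
  L <- profile$L
  out_density <- out_mask <- list()
  for (chrom in names(profile$density)) {
    n <- profile$chrom_sizes[[chrom]]
    tp <- track$track[[chrom]]$plus
    tm <- track$track[[chrom]]$minus
    # plus-strand window: mappable plus starts in [p-L+1, p]
    wp <- window_count_left(tp, L)
    # minus-strand "upstream" is rightward: mappable minus 5' starts in [p, p+L-1]
    wm <- rev(window_count_left(rev(tm), L))
    dp <- profile$density[[chrom]]$plus
    dm <- profile$density[[chrom]]$minus
    if (pre_sum) {
      wtot <- wp + wm
      mask <- wtot == 0L
      dens <- (dp + dm) / (wtot / (2 * L))
    } else {
      mask <- wp == 0L | wm == 0L
      np <- dp / (wp / L)
      nm <- dm / (wm / L)
      dens <- np + nm
    }
    dens[mask] <- NA_real_
    out_density[[chrom]] <- dens
    out_mask[[chrom]] <- mask
  }
  structure(list(density = out_density, mask = out_mask,
                 chrom_sizes = profile$chrom_sizes, L = L,
                 normalized = TRUE, n_truncated = profile$n_truncated),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("<occupancy_profile> %d chromosome(s), L = %d, %s\n",
              length(x$density), x$L,
              if (isTRUE(x$normalized)) "normalized" else "raw per-strand"))
  invisible(x)
}

#' Correlate two occupancy profiles across species
#'
#' Transfers the query profile onto the reference genome position-by-position
#' through a one-to-one filtered chain map and computes a single Pearson
#' correlation over the concatenated chromosome vectors, excluding reference
#' positions that lack an unambiguous mapping or are mappability-masked in
#' either species.
#'
#' @param profile_ref Normalized `occupancy_profile` on the reference genome.
#' @param profile_query Normalized `occupancy_profile` on the query genome.
#' @param map A [chain_map()] from reference to query, one-to-one filtered.
#' @return A list with `r` (Pearson correlation) and `n_positions` used.
#' @export
correlate_profiles <- function(profile_ref, profile_query, map) {
  stopifnot(inherits(profile_ref, "occupancy_profile"),
            inherits(profile_query, "occupancy_profile"),
            inherits(map, "chain_map"))
  if (!isTRUE(profile_ref$normalized) || !isTRUE(profile_query$normalized)) {
    stop_netdecay("profiles must be normalized before correlation",
                  class = "netdecay_contract_error")
  }
  xs <- ys <- list()
  for (chrom in names(profile_ref$density)) {
    n <- profile_ref$chrom_sizes[[chrom]]
    mp <- map_positions(map, chrom, 0:(n - 1L))
    ok <- !is.na(mp$q_pos)
    if (!any(ok)) next
    x <- profile_ref$density[[chrom]]
    qd <- profile_query$density
    y <- rep(NA_real_, n)
    for (qc in unique(mp$q_chrom[ok])) {
      sel <- ok & mp$q_chrom == qc
      y[sel] <- qd[[qc]][mp$q_pos[sel] + 1L]
    }
    use <- ok & !is.na(x) & !is.na(y)
    xs[[chrom]] <- x[use]
    ys[[chrom]] <- y[use]
  }
  x <- unlist(xs, use.names = FALSE)
  y <- unlist(ys, use.names = FALSE)
  if (length(x) < 2L) {
    stop_netdecay("fewer than 2 usable positions", class = "netdecay_empty_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_netdecay("zero variance; correlation undefined")
  }
  list(r = stats::cor(x, y), n_positions = length(x))
}

#' Full nucleotide-resolution occupancy profile from reads
#'
#' Convenience pipeline: PCR-duplicate removal (optional), fragment-size
#' estimation (unless `L` is given), fragment imputation and mappability
#' normalization.
#'
#' @param reads tagAlign tibble (one or more replicates in a list are merged
#'   by adding density vectors).
#' @param track A [mappability_track()] for the genome and read length.
#' @param L Fragment size; estimated from the reads when `NULL`.
#' @param dedup Remove PCR duplicates first (default `TRUE`).
#' @param max_offset Search bound for fragment-size estimation.
#' @return A normalized `occupancy_profile`.
#' @export
occupancy_pipeline <- function(reads, track, L = NULL, dedup = TRUE,
                               max_offset = 400) {
  if (!is.list(reads) || is.data.frame(reads)) reads <- list(reads)
  if (dedup) reads <- lapply(reads, dedup_reads)
  chrom_sizes <- track$chrom_sizes
  if (is.null(L)) {
    merged <- dplyr::bind_rows(reads)
    est <- estimate_fragment_size(start_site_density(merged, chrom_sizes),
                                  max_offset = max_offset,
                                  read_length = track$read_length)
    L <- est$L
  }
  profs <- lapply(reads, impute_density, L = L, chrom_sizes = chrom_sizes)
  merged_prof <- do.call(merge_profiles, profs)
  normalize_density(merged_prof, track)
}
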