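#' Implant PWM matches into a genome
#'
#' Writes `n_sites` motif instances, each sampled position-by-position from
#' the PWM's probability columns, at non-overlapping uniformly random
#' positions of the genome (rejection sampling). Returns the modified genome
#' and a BED tibble of the ground-truth implant locations, the substrate for
#' testing motif scanning and retention.
#'
#' @param genome A `DNAStringSet`.
#' @param pwm A `pwm`.
#' @param n_sites Number of instances to implant.
#' @return A list with `genome` (modified `DNAStringSet`) and `sites` (tibble
#'   `chrom`, `start`, `end`, `strand`, `instance`).
#' @export
implant_motifs <- function(genome, pwm, n_sites) {
  stopifnot(inherits(pwm, "pwm"), n_sites >= 0)
  w <- ncol(pwm)
  sizes <- Biostrings::width(genome)
  if (any(w >= sizes)) stop_netdecay("PWM longer than a chromosome")
  if (n_sites == 0L) {
    return(list(genome = genome,
                sites = tibble::tibble(chrom = character(), start = integer(),
                                       end = integer(), strand = character(),
                                       instance = character())))
  }
  if (n_sites * w * 2L > sum(sizes)) {
    stop_netdecay("not enough genome space for requested implants")
  }
  probs <- attr(pwm, "probs")
  # rejection-sample non-overlapping placements
  occupied <- stats::setNames(vector("list", length(genome)), names(genome))
  placed_chrom <- character(n_sites)
  placed_start <- integer(n_sites)
  n_placed <- 0L
  attempts <- 0L
  while (n_placed < n_sites) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_sites) {
      stop_netdecay("could not place non-overlapping implants")
    }
    ci <- sample.int(length(genome), 1L, prob = sizes / sum(sizes))
    chrom <- names(genome)[ci]
    s <- sample.int(sizes[ci] - w + 1L, 1L) - 1L
    occ <- occupied[[chrom]]
    if (!is.null(occ) && any(s < occ[, 2L] & s + w > occ[, 1L])) next
    occupied[[chrom]] <- rbind(occ, c(s, s + w))
    n_placed <- n_placed + 1L
    placed_chrom[n_placed] <- chrom
    placed_start[n_placed] <- s
  }
  placed <- tibble::tibble(chrom = placed_chrom, start = placed_start)
  instances <- vapply(seq_len(n_sites), function(i) {
    paste(c("A", "C", "G", "T")[apply(probs, 2L, function(p)
      sample.int(4L, 1L, prob = p))], collapse = "")
  }, character(1))
  seqs <- as.character(genome)
  for (i in seq_len(n_sites)) {
    s <- placed$start[i]
    chrom <- placed$chrom[i]
    substr(seqs[[chrom]], s + 1L, s + w) <- instances[i]
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  list(genome = out,
       sites = tibble::tibble(chrom = placed$chrom, start = placed$start,
                              end = placed$start + w, strand = "+",
                              instance = instances))
}
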