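# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most direct method available (full DP tables,
# exhaustive enumeration, per-base scans) and share no code with the package
# internals they check.

# --- simple linear regression via explicit normal equations ------------------
oracle_ols <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1L], slope = beta[2L], rss = sum(res^2))
}

# --- Smith-Waterman local alignment, affine gaps, full DP tables -------------
# gap of length L costs open + L * ext (the Biostrings convention)
oracle_sw <- function(a, b, mat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  M <- Ix <- Iy <- matrix(-Inf, n + 1L, m + 1L)
  M[1L, ] <- M[, 1L] <- 0
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1L, j + 1L] <- max(0,
                               M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                Ix[i, j + 1L] - ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                Iy[i + 1L, j] - ext)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# --- exhaustive PWM score distribution ---------------------------------------
# returns sorted tibble of all 4^w word scores with background probabilities
oracle_pwm_words <- function(pwm, background = attr(pwm, "background")) {
  m <- unclass(pwm)
  w <- ncol(m)
  scores <- 0
  probs <- 1
  for (j in seq_len(w)) {
    scores <- as.vector(outer(scores, m[, j], `+`))
    probs <- as.vector(outer(probs, background, `*`))
  }
  ord <- order(scores)
  data.frame(score = scores[ord], prob = probs[ord])
}

oracle_pwm_cutoff <- function(pwm, alpha) {
  d <- oracle_pwm_words(pwm)
  tail_p <- rev(cumsum(rev(d$prob)))
  ok <- which(tail_p < alpha)
  if (length(ok) == 0L) return(max(d$score) + 1e-4)
  d$score[ok[1L]]
}

# --- per-base greedy chain overlap resolution --------------------------------
# emulates highest-score-first claiming at single-base granularity
oracle_one_to_one_pairs <- function(map) {
  b <- map$blocks
  ord <- unique(b[order(-b$score, b$chain_id), c("chain_id", "score")])
  claimed_ref <- claimed_q <- list()
  pairs <- list()
  for (cid in ord$chain_id) {
    cb <- b[b$chain_id == cid, , drop = FALSE]
    for (bi in seq_len(nrow(cb))) {
      blk <- cb[bi, ]
      for (p in seq.int(blk$ref_start, blk$ref_end - 1L)) {
        q <- if (blk$q_strand == "+") {
          blk$q_start + (p - blk$ref_start)
        } else {
          blk$q_end - 1L - (p - blk$ref_start)
        }
        rk <- paste0(blk$ref_chrom, ":", p)
        qk <- paste0(blk$q_chrom, ":", q)
        if (!is.null(claimed_ref[[rk]]) || !is.null(claimed_q[[qk]])) next
        claimed_ref[[rk]] <- TRUE
        claimed_q[[qk]] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(rk, qk)
      }
    }
  }
  out <- do.call(rbind, pairs)
  out[order(out[, 1L]), , drop = FALSE]
}

# expand a chain_map into per-base (ref, query) pairs
chain_map_pairs <- function(map) {
  b <- map$blocks
  pairs <- list()
  for (bi in seq_len(nrow(b))) {
    blk <- b[bi, ]
    p <- seq.int(blk$ref_start, blk$ref_end - 1L)
    q <- if (blk$q_strand == "+") {
      blk$q_start + (p - blk$ref_start)
    } else {
      blk$q_end - 1L - (p - blk$ref_start)
    }
    pairs[[bi]] <- cbind(paste0(blk$ref_chrom, ":", p),
                         paste0(blk$q_chrom, ":", q))
  }
  out <- do.call(rbind, pairs)
  out[order(out[, 1L]), , drop = FALSE]
}

# --- random chain set generator for fuzzing ----------------------------------
random_chain_set <- function(n_chains = 4L, ref_len = 500L, q_len = 700L,
                             max_blocks = 4L) {
  blocks <- list()
  for (cid in seq_len(n_chains)) {
    nb <- sample.int(max_blocks, 1L)
    rs <- sort(sample.int(ref_len - 30L, nb))
    re <- pmin.int(rs + sample.int(10L, nb) + 2L, ref_len)
    keep <- logical(nb)
    last_end <- -1L
    for (k in seq_len(nb)) {
      if (rs[k] >= last_end) {
        keep[k] <- TRUE
        last_end <- re[k]
      }
    }
    rs <- rs[keep]; re <- re[keep]; nb <- length(rs)
    strand <- sample(c("+", "-"), 1L)
    qw <- re - rs
    gaps <- if (nb > 1L) sample.int(4L, nb - 1L, replace = TRUE) else integer(0)
    qs0 <- sample.int(q_len - sum(qw) - sum(gaps) - 10L, 1L) - 1L
    # ascending query offsets as ref ascends (in strand coordinates)
    qs_strand <- qs0 + cumsum(c(0L, qw[-nb] + gaps))
    if (strand == "+") {
      qs <- qs_strand
    } else {
      # reflect strand coordinates onto forward coordinates
      qs <- q_len - (qs_strand + qw)
    }
    blocks[[cid]] <- tibble::tibble(
      chain_id = cid, score = sample.int(1000L, 1L),
      ref_chrom = "chr1", ref_start = rs, ref_end = re,
      q_chrom = "chr1", q_start = qs, q_end = qs + qw, q_strand = strand
    )
  }
  chain_map(dplyr::bind_rows(blocks), c(chr1 = ref_len), c(chr1 = q_len))
}

# --- brute-force per-position PWM scan ---------------------------------------
oracle_scan <- function(seq_chr, pwm, cutoff) {
  m <- unclass(pwm)
  w <- ncol(m)
  letters <- strsplit(seq_chr, "")[[1L]]
  n <- length(letters)
  hits <- list()
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  for (p in seq_len(n - w + 1L)) {
    word <- letters[p:(p + w - 1L)]
    if (any(!word %in% c("A", "C", "G", "T"))) next
    sf <- sum(m[cbind(match(word, rownames(m)), seq_len(w))])
    wrc <- rev(unname(rc[word]))
    sr <- sum(m[cbind(match(wrc, rownames(m)), seq_len(w))])
    if (sf >= cutoff) hits[[length(hits) + 1L]] <- c(p - 1L, "+")
    if (sr >= cutoff) hits[[length(hits) + 1L]] <- c(p - 1L, "-")
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), strand = character()))
  }
  out <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  names(out) <- c("start", "strand")
  out$start <- as.integer(out$start)
  out[order(out$start, out$strand), ]
}

# --- brute-force mappability -------------------------------------------------
oracle_mappable_plus <- function(seq_chr, k) {
  n <- nchar(seq_chr)
  kmers <- substring(seq_chr, 1:(n - k + 1L), k:n)
  rc_full <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
  rc_kmers <- substring(rc_full, 1:(n - k + 1L), k:n)
  vapply(seq_along(kmers), function(i) {
    w <- kmers[i]
    sum(kmers == w) + sum(rc_kmers == w) == 1L
  }, logical(1))
}

random_genome_for_tests <- function(n, chrom = "chr1") {
  Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    chrom))
}
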