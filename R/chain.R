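#' Chain maps: blockwise coordinate correspondence between two genomes
#'
#' A `chain_map` holds scored chains of ungapped aligned blocks between a
#' reference and a query genome, in the UCSC chain convention. Internally all
#' block coordinates are stored 0-based half-open on the *forward* strand of
#' both genomes; for minus-strand chains the original reversed query
#' coordinates are reconstructed on write. Within a block, reference position
#' `p` maps to `q_start + (p - ref_start)` on plus-strand chains and to
#' `q_end - 1 - (p - ref_start)` on minus-strand chains.
#'
#' @param blocks A data frame with columns `chain_id`, `score`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `q_chrom`, `q_start`, `q_end`, `q_strand`.
#' @param ref_sizes,q_sizes Named integer vectors of chromosome sizes.
#' @return An object of class `chain_map`.
#' @export
chain_map <- function(blocks, ref_sizes, q_sizes) {
  blocks <- tibble::as_tibble(blocks)
  need <- c("chain_id", "score", "ref_chrom", "ref_start", "ref_end",
            "q_chrom", "q_start", "q_end", "q_strand")
  if (!all(need %in% names(blocks))) {
    stop_netdecay(paste0("chain blocks need columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(blocks) > 0) {
    stopifnot(all(blocks$ref_end > blocks$ref_start),
              all(blocks$q_end > blocks$q_start),
              all(blocks$ref_end - blocks$ref_start ==
                    blocks$q_end - blocks$q_start),
              all(blocks$q_strand %in% c("+", "-")))
  }
  blocks <- dplyr::arrange(blocks, .data$chain_id, .data$ref_chrom, .data$ref_start)
  structure(list(blocks = blocks,
                 ref_sizes = ref_sizes, q_sizes = q_sizes),
            class = "chain_map")
}

#' @export
print.chain_map <- function(x, ...) {
  cat(sprintf("<chain_map> %d chain(s), %d block(s), %s aligned bases\n",
              length(unique(x$blocks$chain_id)), nrow(x$blocks),
              format(sum(x$blocks$ref_end - x$blocks$ref_start), big.mark = ",")))
  invisible(x)
}

#' Read a UCSC chain file
#'
#' Parses the standard `chain` text format (header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id`, followed by `size dt dq` block lines, last block `size` only).
#' Minus-strand query coordinates are reflected onto the forward strand for
#' internal storage. Block sizes and gaps are checked against the header
#' spans; a mismatch is a parse error reporting the offending line.
#'
#' @param path Path to a chain file.
#' @return A [chain_map()].
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^chain\\b", lines)
  if (length(hdr_idx) == 0L) stop_netdecay("no chain records found")
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr_idx))
  ref_sizes <- q_sizes <- integer()
  for (ci in seq_along(hdr_idx)) {
    h <- strsplit(trimws(lines[hdr_idx[ci]]), "\\s+")[[1L]]
    if (length(h) < 12L) {
      stop_netdecay(sprintf("malformed chain header at line %d", hdr_idx[ci]))
    }
    score <- as.numeric(h[2L])
    t_name <- h[3L]; t_size <- as.integer(h[4L])
    t_start <- as.integer(h[6L]); t_end <- as.integer(h[7L])
    q_name <- h[8L]; q_size <- as.integer(h[9L]); q_strand <- h[10L]
    q_start <- as.integer(h[11L]); q_end <- as.integer(h[12L])
    id <- if (length(h) >= 13L) as.integer(h[13L]) else ci
    body <- lines[(hdr_idx[ci] + 1L):ends[ci]]
    mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
    sizes <- mat[, 1L]
    dt <- if (ncol(mat) >= 2L) mat[, 2L] else integer(0)
    dq <- if (ncol(mat) >= 3L) mat[, 3L] else integer(0)
    dt[nrow(mat)] <- dq[nrow(mat)] <- 0L
    if (sum(sizes) + sum(dt) != t_end - t_start ||
        sum(sizes) + sum(dq) != q_end - q_start) {
      stop_netdecay(sprintf(
        "block sizes inconsistent with header spans for chain at line %d",
        hdr_idx[ci]))
    }
    rs <- t_start + c(0L, cumsum(sizes + dt)[-length(sizes)])
    qs <- q_start + c(0L, cumsum(sizes + dq)[-length(sizes)])
    if (q_strand == "+") {
      qf_s <- qs; qf_e <- qs + sizes
    } else {
      # header query coords are on the reversed strand: reflect
      qf_s <- q_size - (qs + sizes); qf_e <- q_size - qs
    }
    out[[ci]] <- tibble::tibble(
      chain_id = id, score = score,
      ref_chrom = t_name, ref_start = rs, ref_end = rs + sizes,
      q_chrom = q_name, q_start = qf_s, q_end = qf_e, q_strand = q_strand
    )
    ref_sizes[t_name] <- t_size
    q_sizes[q_name] <- q_size
  }
  chain_map(dplyr::bind_rows(out), ref_sizes, q_sizes)
}

#' Write a chain map as a UCSC chain file
#'
#' @param map A [chain_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(map, path) {
  stopifnot(inherits(map, "chain_map"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(map$blocks$chain_id)) {
    b <- map$blocks[map$blocks$chain_id == id, , drop = FALSE]
    b <- b[order(b$ref_start), , drop = FALSE]
    strand <- b$q_strand[1L]
    t_name <- b$ref_chrom[1L]; q_name <- b$q_chrom[1L]
    t_size <- map$ref_sizes[[t_name]]; q_size <- map$q_sizes[[q_name]]
    sizes <- b$ref_end - b$ref_start
    if (strand == "+") {
      qs <- b$q_start; qe <- b$q_end
    } else {
      # reflect forward coords back to reversed-strand coords; with blocks in
      # ref order the reversed-strand query coords are ascending too
      qs <- q_size - b$q_end; qe <- q_size - b$q_start
    }
    t_start <- b$ref_start[1L]; t_end <- b$ref_end[nrow(b)]
    q_start <- qs[1L]; q_end <- qe[nrow(b)]
    n <- nrow(b)
    dt <- if (n > 1L) b$ref_start[-1L] - b$ref_end[-n] else integer(0)
    dq <- if (n > 1L) qs[-1L] - qe[-n] else integer(0)
    if (any(dt < 0) || any(dq < 0)) {
      stop_netdecay(sprintf("chain %s has out-of-order blocks", id))
    }
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                       format(b$score[1L], scientific = FALSE, trim = TRUE),
                       t_name, t_size, t_start, t_end,
                       q_name, q_size, strand, q_start, q_end, id), con)
    if (n > 1L) {
      writeLines(sprintf("%d %d %d", sizes[-n], dt, dq), con)
    }
    writeLines(sprintf("%d", sizes[n]), con)
    writeLines("", con)
  }
  invisible(path)
}

# remove [cs, ce) pieces from [s, e); returns matrix of kept (start, end)
subtract_intervals <- function(s, e, claimed) {
  s <- unname(s); e <- unname(e)
  if (is.null(claimed) || nrow(claimed) == 0L) {
    return(matrix(c(s, e), ncol = 2L))
  }
  cl <- claimed[claimed[, 2L] > s & claimed[, 1L] < e, , drop = FALSE]
  if (nrow(cl) == 0L) return(matrix(c(s, e), ncol = 2L))
  cl <- cl[order(cl[, 1L]), , drop = FALSE]
  keep_s <- integer(0); keep_e <- integer(0)
  cur <- s
  for (i in seq_len(nrow(cl))) {
    if (cl[i, 1L] > cur) {
      keep_s <- c(keep_s, cur); keep_e <- c(keep_e, min(cl[i, 1L], e))
    }
    cur <- max(cur, cl[i, 2L])
    if (cur >= e) break
  }
  if (cur < e) {
    keep_s <- c(keep_s, cur); keep_e <- c(keep_e, e)
  }
  matrix(c(unname(keep_s), unname(keep_e)), ncol = 2L)
}

# forward query sub-interval corresponding to ref sub-interval of a block
block_q_sub <- function(block, s, e) {
  if (block$q_strand == "+") {
    c(block$q_start + (s - block$ref_start), block$q_start + (e - block$ref_start))
  } else {
    c(block$q_end - (e - block$ref_start), block$q_end - (s - block$ref_start))
  }
}

#' Filter a chain map to one-to-one coverage
#'
#' Resolves overlapping chains so that every reference position and every
#' query position is covered by at most one block: chains are processed in
#' decreasing score order (ties broken by chain id for determinism) and each
#' chain keeps only the block portions not already claimed, on either genome,
#' by a higher-scoring chain. This reproduces the "retain only the highest
#' scoring alignment for each position" filtering used before transferring
#' nucleotide-resolution data between species.
#'
#' @param map A [chain_map()].
#' @return A [chain_map()] with non-overlapping blocks on both genomes.
#' @export
filter_one_to_one <- function(map) {
  stopifnot(inherits(map, "chain_map"))
  b <- map$blocks
  if (nrow(b) == 0L) return(map)
  chain_order <- b |>
    dplyr::distinct(.data$chain_id, .data$score) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$chain_id)
  claimed_ref <- list()   # per ref chrom: matrix (start, end)
  claimed_q <- list()     # per query chrom
  kept <- vector("list", nrow(chain_order))
  for (ci in seq_len(nrow(chain_order))) {
    cb <- b[b$chain_id == chain_order$chain_id[ci], , drop = FALSE]
    pieces <- vector("list", nrow(cb))
    for (bi in seq_len(nrow(cb))) {
      blk <- cb[bi, , drop = FALSE]
      # subtract claimed reference intervals
      ref_keep <- subtract_intervals(blk$ref_start, blk$ref_end,
                                     claimed_ref[[blk$ref_chrom]])
      sub <- vector("list", nrow(ref_keep))
      for (ri in seq_len(nrow(ref_keep))) {
        s <- ref_keep[ri, 1L]; e <- ref_keep[ri, 2L]
        qi <- block_q_sub(blk, s, e)
        # subtract claimed query intervals (map kept query pieces back to ref)
        q_keep <- subtract_intervals(qi[1L], qi[2L], claimed_q[[blk$q_chrom]])
        if (nrow(q_keep) == 0L) next
        if (blk$q_strand == "+") {
          rs2 <- s + (q_keep[, 1L] - qi[1L]); re2 <- s + (q_keep[, 2L] - qi[1L])
        } else {
          rs2 <- s + (qi[2L] - q_keep[, 2L]); re2 <- s + (qi[2L] - q_keep[, 1L])
        }
        sub[[ri]] <- tibble::tibble(
          chain_id = blk$chain_id, score = blk$score,
          ref_chrom = blk$ref_chrom, ref_start = rs2, ref_end = re2,
          q_chrom = blk$q_chrom, q_start = q_keep[, 1L], q_end = q_keep[, 2L],
          q_strand = blk$q_strand
        )
      }
      pieces[[bi]] <- dplyr::bind_rows(sub)
    }
    chain_kept <- dplyr::bind_rows(pieces)
    kept[[ci]] <- chain_kept
    if (nrow(chain_kept) > 0L) {
      for (chrom in unique(chain_kept$ref_chrom)) {
        m <- as.matrix(chain_kept[chain_kept$ref_chrom == chrom,
                                  c("ref_start", "ref_end")])
        claimed_ref[[chrom]] <- rbind(claimed_ref[[chrom]], unname(m))
      }
      for (chrom in unique(chain_kept$q_chrom)) {
        m <- as.matrix(chain_kept[chain_kept$q_chrom == chrom,
                                  c("q_start", "q_end")])
        claimed_q[[chrom]] <- rbind(claimed_q[[chrom]], unname(m))
      }
    }
  }
  chain_map(dplyr::bind_rows(kept), map$ref_sizes, map$q_sizes)
}

#' Invert a chain map
#'
#' Swaps the reference and query genomes, so lifted intervals can be mapped
#' back.
#'
#' @param map A [chain_map()].
#' @return A [chain_map()] from the query genome to the reference genome.
#' @export
invert_chain_map <- function(map) {
  stopifnot(inherits(map, "chain_map"))
  b <- map$blocks
  inv <- tibble::tibble(
    chain_id = b$chain_id, score = b$score,
    ref_chrom = b$q_chrom, ref_start = b$q_start, ref_end = b$q_end,
    q_chrom = b$ref_chrom, q_start = b$ref_start, q_end = b$ref_end,
    q_strand = b$q_strand
  )
  chain_map(inv, map$q_sizes, map$ref_sizes)
}

#' Lift reference intervals to query coordinates through a chain map
#'
#' LiftOver-style interval transfer: an interval succeeds if at least
#' `min_match` of its bases fall within the blocks of a single chain (the
#' chain with most aligned bases; LiftOver semantics, not summed across
#' chains), and the spanning query interval is no longer than
#' `max_target_span` base pairs. Failures carry a reason:
#' `"no_alignment"`, `"below_min_match"` or `"span_too_long"`.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). Extra columns are preserved.
#' @param map A [chain_map()].
#' @param min_match Minimum fraction of bases that must remap, in (0, 1].
#'   0.001 reproduces the "none" setting; 0.95 is the stringent default of the
#'   LiftOver tool.
#' @param max_target_span Maximum allowed query span in bp (default 1000,
#'   matching the exclusion of segments that map to a region longer than
#'   1000 bp); `Inf` disables the check.
#' @return The input tibble with added columns `lifted` (logical), `reason`,
#'   `q_chrom`, `q_start`, `q_end`, `q_strand`, `aligned_bases`.
#' @export
lift_intervals <- function(intervals, map, min_match = 0.001,
                           max_target_span = 1000) {
  stopifnot(inherits(map, "chain_map"), min_match > 0, min_match <= 1)
  iv <- tibble::as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  bad <- !iv$chrom %in% names(map$ref_sizes) |
    iv$start < 0 | iv$end > map$ref_sizes[iv$chrom] | iv$end <= iv$start
  if (any(bad)) {
    stop_netdecay("interval outside reference chromosome bounds",
                  class = "netdecay_bounds_error")
  }
  n <- nrow(iv)
  iv$lifted <- FALSE
  iv$reason <- "no_alignment"
  iv$q_chrom <- NA_character_
  iv$q_start <- NA_integer_
  iv$q_end <- NA_integer_
  iv$q_strand <- NA_character_
  iv$aligned_bases <- 0L
  b <- map$blocks
  if (nrow(b) == 0L || n == 0L) return(iv)

  # overlap join blocks x intervals per chromosome via IRanges
  for (chrom in unique(iv$chrom)) {
    ii <- which(iv$chrom == chrom)
    bb <- which(b$ref_chrom == chrom)
    if (length(bb) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(iv$start[ii] + 1L, iv$end[ii]),
      IRanges::IRanges(b$ref_start[bb] + 1L, b$ref_end[bb])
    )
    if (length(hits) == 0L) next
    qi <- ii[S4Vectors::queryHits(hits)]
    bi <- bb[S4Vectors::subjectHits(hits)]
    ow <- overlap_width(iv$start[qi], iv$end[qi], b$ref_start[bi], b$ref_end[bi])
    per <- tibble::tibble(iv_row = qi, block = bi,
                          chain_id = b$chain_id[bi], w = ow) |>
      dplyr::group_by(.data$iv_row, .data$chain_id) |>
      dplyr::mutate(chain_w = sum(.data$w)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$iv_row) |>
      dplyr::filter(.data$chain_w == max(.data$chain_w)) |>
      dplyr::filter(.data$chain_id == min(.data$chain_id)) |>
      dplyr::ungroup()
    s <- pmax.int(iv$start[per$iv_row], b$ref_start[per$block])
    e <- pmin.int(iv$end[per$iv_row], b$ref_end[per$block])
    plus <- b$q_strand[per$block] == "+"
    q_lo <- ifelse(plus,
                   b$q_start[per$block] + (s - b$ref_start[per$block]),
                   b$q_end[per$block] - (e - b$ref_start[per$block]))
    q_hi <- ifelse(plus,
                   b$q_start[per$block] + (e - b$ref_start[per$block]),
                   b$q_end[per$block] - (s - b$ref_start[per$block]))
    summ <- tibble::tibble(iv_row = per$iv_row, chain_w = per$chain_w,
                           q_chrom = b$q_chrom[per$block],
                           q_strand = b$q_strand[per$block],
                           q_lo = q_lo, q_hi = q_hi) |>
      dplyr::group_by(.data$iv_row) |>
      dplyr::summarise(aligned = .data$chain_w[1L],
                       q_chrom = .data$q_chrom[1L],
                       q_strand = .data$q_strand[1L],
                       q_lo = min(.data$q_lo), q_hi = max(.data$q_hi),
                       .groups = "drop")
    rows <- summ$iv_row
    iv$aligned_bases[rows] <- summ$aligned
    width <- iv$end[rows] - iv$start[rows]
    pass_mm <- summ$aligned / width >= min_match
    pass_span <- summ$q_hi - summ$q_lo <= max_target_span
    iv$reason[rows[!pass_mm]] <- "below_min_match"
    iv$reason[rows[pass_mm & !pass_span]] <- "span_too_long"
    ok2 <- pass_mm & pass_span
    iv$lifted[rows[ok2]] <- TRUE
    iv$reason[rows[ok2]] <- "ok"
    iv$q_chrom[rows[ok2]] <- summ$q_chrom[ok2]
    iv$q_start[rows[ok2]] <- as.integer(summ$q_lo[ok2])
    iv$q_end[rows[ok2]] <- as.integer(summ$q_hi[ok2])
    iv$q_strand[rows[ok2]] <- summ$q_strand[ok2]
  }
  iv
}

#' @rdname lift_intervals
#' @param chrom,start,end A single interval.
#' @export
lift_interval <- function(chrom, start, end, map, min_match = 0.001,
                          max_target_span = 1000) {
  lift_intervals(tibble::tibble(chrom = chrom, start = start, end = end),
                 map, min_match = min_match, max_target_span = max_target_span)
}

#' Map single reference positions to query positions
#'
#' Position-wise transfer through a (typically one-to-one filtered) chain map.
#' Positions falling in no block, or in blocks of more than one chain when the
#' map is ambiguous, return `NA`. Used to transfer per-nucleotide occupancy
#' vectors onto the reference genome.
#'
#' @param map A [chain_map()]; should be one-to-one filtered for unambiguous
#'   output.
#' @param chrom Reference chromosome name.
#' @param positions Integer vector of 0-based reference positions.
#' @return A tibble with `q_chrom`, `q_pos`, `q_strand` (`NA` where unmapped).
#' @export
map_positions <- function(map, chrom, positions) {
  stopifnot(inherits(map, "chain_map"))
  b <- map$blocks[map$blocks$ref_chrom == chrom, , drop = FALSE]
  out <- tibble::tibble(q_chrom = rep(NA_character_, length(positions)),
                        q_pos = rep(NA_integer_, length(positions)),
                        q_strand = rep(NA_character_, length(positions)))
  if (nrow(b) == 0L) return(out)
  b <- b[order(b$ref_start), , drop = FALSE]
  idx <- findInterval(positions, b$ref_start)
  ok <- idx >= 1L & positions < b$ref_end[pmax(idx, 1L)]
  if (!any(ok)) return(out)
  bi <- idx[ok]
  p <- positions[ok]
  plus <- b$q_strand[bi] == "+"
  qp <- integer(length(p))
  qp[plus] <- b$q_start[bi[plus]] + (p[plus] - b$ref_start[bi[plus]])
  qp[!plus] <- b$q_end[bi[!plus]] - 1L - (p[!plus] - b$ref_start[bi[!plus]])
  out$q_chrom[ok] <- b$q_chrom[bi]
  out$q_pos[ok] <- qp
  out$q_strand[ok] <- b$q_strand[bi]
  out
}
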