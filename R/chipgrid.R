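#' The segment-resolution analysis choice grid
#'
#' Cross-species comparison of GSTF-occupied segments involves five analytical
#' choices; this function enumerates the full factorial grid:
#'
#' * `peak_caller`: `M` / `S` — two variants of the internal Poisson
#'   enrichment caller (different window sizes; see [call_peaks_standin()]);
#' * `quality`: `S`tringent (stringent calls, replicates intersected),
#'   `L`enient (lenient calls, replicates merged), `A`symmetric (stringent in
#'   the reference species, lenient in the query);
#' * `min_match`: LiftOver minMatch `S` = 0.95, `L` = 0.5, `N` = 0.001;
#' * `reference_subset`: `A`ll reference segments, `P`air-mappable only,
#'   `S`hared across all species of the lineage;
#' * `overlap`: `L`enient (1 bp) or `S`tringent (reciprocal 50%).
#'
#' @return A 108-row tibble, one row per pipeline, with a `pipeline` id.
#' @export
pipeline_choices <- function() {
  grid <- tidyr::expand_grid(
    peak_caller = c("M", "S"),
    quality = c("S", "L", "A"),
    min_match = c("S", "L", "N"),
    reference_subset = c("A", "P", "S"),
    overlap = c("L", "S")
  )
  grid$pipeline <- sprintf("%s%s%s%s%s", grid$peak_caller, grid$quality,
                           grid$min_match, grid$reference_subset, grid$overlap)
  grid
}

min_match_value <- function(code) {
  c(S = 0.95, L = 0.5, N = 0.001)[[code]]
}

#' Poisson-enrichment stand-in peak caller
#'
#' Discretizes an occupancy read set into occupied segments by a sliding-
#' window Poisson test of ChIP counts against a depth-scaled control.
#' Two caller variants differ in window size (`M`: 150 bp, `S`: 300 bp), so
#' the caller axis of the pipeline grid changes results, and two significance
#' tiers mirror common practice: `lenient` at p < 1e-5 and `stringent` at
#' p < 1e-22 for variant `M`; for variant `S` the stringent tier keeps the
#' top-scoring tie class of windows. Adjacent significant windows are merged.
#' External peak callers are deliberately not reimplemented; the grid's point
#' is sensitivity to choices, which the stand-in preserves.
#'
#' @param reads tagAlign tibble of ChIP reads.
#' @param control tagAlign tibble of control reads, or `NULL` to use the
#'   global background rate.
#' @param chrom_sizes Named integer vector.
#' @param tier `"lenient"` or `"stringent"`.
#' @param caller `"M"` or `"S"`.
#' @param fragment_size Shift applied to estimate fragment midpoints (bp).
#' @return A `PeakSet`-style tibble: `chrom`, `start`, `end`, `score`
#'   (-log10 p of the best window), sorted and non-overlapping.
#' @export
call_peaks_standin <- function(reads, control = NULL, chrom_sizes,
                               tier = c("lenient", "stringent"),
                               caller = c("M", "S"), fragment_size = 200) {
  tier <- match.arg(tier)
  caller <- match.arg(caller)
  win <- if (caller == "M") 150L else 300L
  out <- list()
  n_chip <- nrow(reads)
  n_ctrl <- if (is.null(control)) 0L else nrow(control)
  for (chrom in names(chrom_sizes)) {
    n <- chrom_sizes[[chrom]]
    mids <- function(r) {
      r <- r[r$chrom == chrom, , drop = FALSE]
      m <- ifelse(r$strand == "+", r$start + fragment_size %/% 2L,
                  r$end - fragment_size %/% 2L)
      pmin.int(pmax.int(m, 0L), n - 1L)
    }
    chip_mid <- mids(reads)
    starts <- seq.int(0L, max(n - win, 0L), by = win)
    cnt <- tabulate(findInterval(chip_mid, starts), nbins = length(starts))
    if (!is.null(control) && n_ctrl > 0L) {
      ctrl_mid <- mids(control)
      ctrl_cnt <- tabulate(findInterval(ctrl_mid, starts), nbins = length(starts))
      scale <- n_chip / n_ctrl
      # floor control rate at the global background so empty windows don't
      # produce spurious significance
      lambda <- pmax(ctrl_cnt * scale, n_chip * win / n)
    } else {
      lambda <- rep(n_chip * win / n, length(starts))
    }
    logp <- stats::ppois(cnt - 1L, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
    keep <- if (tier == "lenient") {
      logp < -5
    } else if (caller == "M") {
      logp < -22
    } else {
      sig <- logp < -5
      if (!any(sig)) sig else sig & logp <= min(logp[sig]) + 1e-9
    }
    if (!any(keep)) next
    iv <- IRanges::reduce(IRanges::IRanges(starts[keep] + 1L,
                                           pmin.int(starts[keep] + win, n)))
    sc <- vapply(seq_along(iv), function(i) {
      inwin <- starts + 1L >= IRanges::start(iv)[i] & starts + win <= IRanges::end(iv)[i]
      -min(logp[inwin & keep])
    }, numeric(1))
    out[[chrom]] <- tibble::tibble(chrom = chrom,
                                   start = IRanges::start(iv) - 1L,
                                   end = IRanges::end(iv), score = sc)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), score = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Combine replicate peak sets
#'
#' `merge` unions the intervals of both replicates; `intersect` first merges,
#' then keeps merged segments supported by at least one segment in *each*
#' original replicate.
#'
#' @param peaks_rep1,peaks_rep2 Peak tibbles (`chrom`, `start`, `end`).
#' @param mode `"merge"` or `"intersect"`.
#' @return A combined peak tibble.
#' @export
combine_replicates <- function(peaks_rep1, peaks_rep2,
                               mode = c("merge", "intersect")) {
  mode <- match.arg(mode)
  both <- dplyr::bind_rows(peaks_rep1, peaks_rep2)
  if (nrow(both) == 0L) return(both[, c("chrom", "start", "end")])
  out <- list()
  for (chrom in unique(both$chrom)) {
    b <- both[both$chrom == chrom, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(b$start + 1L, b$end))
    seg <- tibble::tibble(chrom = chrom, start = IRanges::start(merged) - 1L,
                          end = IRanges::end(merged))
    if (mode == "intersect") {
      in1 <- IRanges::overlapsAny(
        merged, with(peaks_rep1[peaks_rep1$chrom == chrom, ],
                     IRanges::IRanges(start + 1L, end)))
      in2 <- IRanges::overlapsAny(
        merged, with(peaks_rep2[peaks_rep2$chrom == chrom, ],
                     IRanges::IRanges(start + 1L, end)))
      seg <- seg[in1 & in2, , drop = FALSE]
    }
    out[[chrom]] <- seg
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Select the reference-occupied segment subset
#'
#' @param ref_peaks Reference peak tibble.
#' @param lift_ok A named list (one element per species in the lineage) of
#'   logical vectors, `TRUE` where the corresponding reference peak lifted to
#'   that species.
#' @param mode `"A"` (all), `"P"` (mappable to `pair_species`), `"S"`
#'   (mappable to every species).
#' @param pair_species Species of the current pair (required for `"P"`).
#' @return The selected subset of `ref_peaks`.
#' @export
select_reference_subset <- function(ref_peaks, lift_ok, mode = c("A", "P", "S"),
                                    pair_species = NULL) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    A = rep(TRUE, nrow(ref_peaks)),
    P = {
      if (is.null(pair_species)) {
        stop_netdecay("mode 'P' needs `pair_species`")
      }
      lift_ok[[pair_species]]
    },
    S = Reduce(`&`, lift_ok)
  )
  ref_peaks[keep, , drop = FALSE]
}

#' Fraction of projected reference segments overlapping query peaks
#'
#' @param projected Projected reference segments in query coordinates
#'   (`chrom`, `start`, `end`).
#' @param query_peaks Query-species peak tibble.
#' @param mode `"L"`: any 1 bp overlap counts; `"S"`: reciprocal overlap of
#'   at least half of each segment's length.
#' @return The fraction in `[0, 1]`.
#' @export
occupancy_overlap_fraction <- function(projected, query_peaks,
                                       mode = c("L", "S")) {
  mode <- match.arg(mode)
  if (nrow(projected) == 0L) {
    stop_netdecay("empty reference subset; overlap fraction undefined",
                  class = "netdecay_empty_error")
  }
  hit <- logical(nrow(projected))
  for (chrom in unique(projected$chrom)) {
    pi <- which(projected$chrom == chrom)
    q <- query_peaks[query_peaks$chrom == chrom, , drop = FALSE]
    if (nrow(q) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(projected$start[pi] + 1L, projected$end[pi]),
      IRanges::IRanges(q$start + 1L, q$end))
    if (length(ov) == 0L) next
    a <- pi[S4Vectors::queryHits(ov)]
    b <- S4Vectors::subjectHits(ov)
    w <- overlap_width(projected$start[a], projected$end[a],
                       q$start[b], q$end[b])
    ok <- if (mode == "L") {
      w >= 1L
    } else {
      w >= 0.5 * (projected$end[a] - projected$start[a]) &
        w >= 0.5 * (q$end[b] - q$start[b])
    }
    hit[unique(a[ok])] <- TRUE
  }
  mean(hit)
}

#' Run the full segment-resolution pipeline grid
#'
#' Executes every pipeline of [pipeline_choices()] (or a subset) on a set of
#' GSTF ChIP experiments and compares divergence rates for every cross-lineage
#' GSTF pair with [compare_rates()].
#'
#' Each experiment is a list describing one GSTF in one lineage:
#' `lineage`, `gstf`, `chrom_sizes` (reference genome), `ref_reads` (list of
#' 1-2 replicate tagAlign tibbles), `ref_control`, and `species`: a named list
#' with, per non-reference species, `reads` (list of replicates), `control`,
#' `chain` (reference -> species [chain_map()]), `chrom_sizes`, and
#' `time_myr`.
#'
#' @param experiments List of experiment descriptions (see Details).
#' @param choices Pipeline grid rows to run (default all 108).
#' @param fragment_size Fragment-size shift used by the stand-in caller.
#' @param alpha,effect_threshold Decision parameters for [compare_rates()].
#' @return A list with `similarities` (tibble: pipeline x experiment x species
#'   retention fractions), `comparisons` (tibble: pipeline x GSTF pair with
#'   p-value, effect size, verdict) and `verdict_shares`.
#' @export
run_chip_grid <- function(experiments, choices = pipeline_choices(),
                          fragment_size = 200, alpha = 0.05,
                          effect_threshold = 5) {
  stopifnot(length(experiments) >= 2L)
  # cache peaks per (experiment, species-or-ref, caller, tier)
  peak_cache <- new.env(parent = emptyenv())
  get_peaks <- function(ei, who, caller, tier) {
    key <- paste(ei, who, caller, tier, sep = "|")
    if (!is.null(peak_cache[[key]])) return(peak_cache[[key]])
    ex <- experiments[[ei]]
    if (who == "ref") {
      reps <- ex$ref_reads; ctrl <- ex$ref_control; cs <- ex$chrom_sizes
    } else {
      reps <- ex$species[[who]]$reads
      ctrl <- ex$species[[who]]$control
      cs <- ex$species[[who]]$chrom_sizes
    }
    called <- lapply(reps, call_peaks_standin, control = ctrl,
                     chrom_sizes = cs, tier = tier, caller = caller,
                     fragment_size = fragment_size)
    peaks <- if (length(called) == 1L) {
      called[[1L]]
    } else {
      combine_replicates(called[[1L]], called[[2L]],
                         mode = if (tier == "stringent") "intersect" else "merge")
    }
    peak_cache[[key]] <- peaks
    peaks
  }
  lift_cache <- new.env(parent = emptyenv())
  get_lift <- function(ei, caller, ref_tier, mm_code) {
    key <- paste(ei, caller, ref_tier, mm_code, sep = "|")
    if (!is.null(lift_cache[[key]])) return(lift_cache[[key]])
    ex <- experiments[[ei]]
    ref_peaks <- get_peaks(ei, "ref", caller, ref_tier)
    lifts <- purrr::imap(ex$species, function(spx, sp) {
      lift_intervals(ref_peaks[, c("chrom", "start", "end")], spx$chain,
                     min_match = min_match_value(mm_code),
                     max_target_span = Inf)
    })
    res <- list(ref_peaks = ref_peaks, lifts = lifts)
    lift_cache[[key]] <- res
    res
  }

  sims <- list()
  for (pi in seq_len(nrow(choices))) {
    ch <- choices[pi, ]
    ref_tier <- if (ch$quality == "L") "lenient" else "stringent"
    q_tier <- if (ch$quality == "S") "stringent" else "lenient"
    for (ei in seq_along(experiments)) {
      ex <- experiments[[ei]]
      lf <- get_lift(ei, ch$peak_caller, ref_tier, ch$min_match)
      lift_ok <- purrr::map(lf$lifts, "lifted")
      for (sp in names(ex$species)) {
        subset_peaks <- select_reference_subset(lf$ref_peaks, lift_ok,
                                                mode = ch$reference_subset,
                                                pair_species = sp)
        sub_lift <- lf$lifts[[sp]][rownames_match(lf$ref_peaks, subset_peaks), ,
                                   drop = FALSE]
        proj <- sub_lift[sub_lift$lifted, , drop = FALSE]
        frac <- if (nrow(subset_peaks) == 0L) {
          NA_real_
        } else if (nrow(proj) == 0L) {
          0
        } else {
          q_peaks <- get_peaks(ei, sp, ch$peak_caller, q_tier)
          # retention is per reference-subset segment: unlifted segments count
          # as not retained
          occupancy_overlap_fraction(
            tibble::tibble(chrom = proj$q_chrom, start = proj$q_start,
                           end = proj$q_end),
            q_peaks, mode = ch$overlap) * nrow(proj) / nrow(subset_peaks)
        }
        sims[[length(sims) + 1L]] <- tibble::tibble(
          pipeline = ch$pipeline, experiment = ei,
          lineage = ex$lineage, gstf = ex$gstf, species = sp,
          divergence_myr = ex$species[[sp]]$time_myr, similarity = frac
        )
      }
    }
  }
  similarities <- dplyr::bind_rows(sims)

  # cross-lineage GSTF pairs
  meta <- purrr::map_dfr(seq_along(experiments), function(ei) {
    tibble::tibble(experiment = ei, lineage = experiments[[ei]]$lineage,
                   gstf = experiments[[ei]]$gstf)
  })
  pairs <- tidyr::expand_grid(a = seq_len(nrow(meta)), b = seq_len(nrow(meta))) |>
    dplyr::filter(.data$a < .data$b) |>
    dplyr::filter(meta$lineage[.data$a] != meta$lineage[.data$b])
  comps <- list()
  for (pl in unique(similarities$pipeline)) {
    sim_pl <- similarities[similarities$pipeline == pl, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      ea <- pairs$a[k]; eb <- pairs$b[k]
      obs <- sim_pl[sim_pl$experiment %in% c(ea, eb), , drop = FALSE]
      obs <- obs[!is.na(obs$similarity) & obs$similarity > 0, , drop = FALSE]
      obs$lineage <- paste(obs$lineage, obs$gstf, sep = ":")
      cmp <- tryCatch(
        suppressWarnings(compare_rates(obs, alpha = alpha,
                                       effect_threshold = effect_threshold)),
        error = function(e) NULL)
      comps[[length(comps) + 1L]] <- tibble::tibble(
        pipeline = pl,
        gstf_a = meta$gstf[ea], gstf_b = meta$gstf[eb],
        p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
        effect_size_pct = if (is.null(cmp)) NA_real_ else cmp$effect_size_pct,
        verdict = if (is.null(cmp)) NA_character_ else cmp$verdict
      )
    }
  }
  comparisons <- dplyr::bind_rows(comps)
  shares <- comparisons |>
    dplyr::filter(!is.na(.data$verdict)) |>
    dplyr::count(.data$gstf_a, .data$gstf_b, .data$verdict) |>
    dplyr::group_by(.data$gstf_a, .data$gstf_b) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(similarities = similarities, comparisons = comparisons,
       verdict_shares = shares)
}

# indices of rows of `subset` within `full` (peak tibbles with identical rows)
rownames_match <- function(full, subset) {
  key_full <- paste(full$chrom, full$start, full$end)
  key_sub <- paste(subset$chrom, subset$start, subset$end)
  match(key_sub, key_full)
}
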