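#' Pair orthologous expression values between two species
#'
#' Joins a reference and a second expression table through a one-to-one
#' ortholog map, keeping genes present in both tables and in the map.
#'
#' @param table_ref,table_other Tibbles with columns `gene_id`, `tpm`.
#' @param ortholog_map Tibble with columns `gene_ref`, `gene_other`; must be
#'   one-to-one (no gene repeated on either side).
#' @return A tibble `gene_ref`, `gene_other`, `tpm_ref`, `tpm_other`.
#' @export
pair_orthologs <- function(table_ref, table_other, ortholog_map) {
  stopifnot(all(c("gene_id", "tpm") %in% names(table_ref)),
            all(c("gene_id", "tpm") %in% names(table_other)),
            all(c("gene_ref", "gene_other") %in% names(ortholog_map)))
  if (anyDuplicated(ortholog_map$gene_ref) ||
      anyDuplicated(ortholog_map$gene_other)) {
    stop_netdecay("ortholog map is not one-to-one",
                  class = "netdecay_contract_error")
  }
  if (anyDuplicated(table_ref$gene_id) || anyDuplicated(table_other$gene_id)) {
    stop_netdecay("gene ids must be unique within a table")
  }
  out <- ortholog_map |>
    dplyr::inner_join(dplyr::rename(table_ref, gene_ref = "gene_id",
                                    tpm_ref = "tpm"), by = "gene_ref") |>
    dplyr::inner_join(dplyr::rename(table_other, gene_other = "gene_id",
                                    tpm_other = "tpm"), by = "gene_other")
  if (nrow(out) == 0L) {
    stop_netdecay("no genes shared between tables and ortholog map",
                  class = "netdecay_empty_error")
  }
  tibble::as_tibble(out)
}

#' Cross-species expression correlation
#'
#' The similarity measure of the expression layer: after discarding gene
#' pairs where either species' abundance is at or below `tpm_floor` TPM
#' (reference-only filtering via `filter_scope = "ref"`; `tpm_floor = NULL`
#' disables the filter), computes Spearman's rank correlation (default),
#' Kendall's tau-b, or Pearson's correlation of log2-transformed values.
#' With the floor active all surviving values exceed 5 TPM so `log2(tpm)` is
#' safe; with the filter off, `log2(tpm + 1)` is used.
#'
#' @param pairs Output of [pair_orthologs()].
#' @param metric `"spearman"`, `"kendall"` or `"pearson_log2"`.
#' @param tpm_floor Abundance floor (drop pairs with a value <= floor);
#'   default 5, `NULL` to disable.
#' @param filter_scope `"either"` (default: drop if either species is at or
#'   below the floor) or `"ref"` (reference only).
#' @return A list with `similarity`, `n_pairs` (after filtering) and `metric`.
#' @export
correlate_expression <- function(pairs, metric = c("spearman", "kendall",
                                                   "pearson_log2"),
                                 tpm_floor = 5,
                                 filter_scope = c("either", "ref")) {
  metric <- match.arg(metric)
  filter_scope <- match.arg(filter_scope)
  stopifnot(all(c("tpm_ref", "tpm_other") %in% names(pairs)))
  x <- pairs$tpm_ref
  y <- pairs$tpm_other
  if (!is.null(tpm_floor)) {
    keep <- if (filter_scope == "either") {
      x > tpm_floor & y > tpm_floor
    } else {
      x > tpm_floor
    }
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 10L) {
    stop_netdecay("fewer than 10 gene pairs after filtering",
                  class = "netdecay_empty_error")
  }
  sim <- switch(metric,
    spearman = stats::cor(x, y, method = "spearman"),
    kendall = stats::cor(x, y, method = "kendall"),
    pearson_log2 = {
      if (is.null(tpm_floor)) {
        stats::cor(log2(x + 1), log2(y + 1))
      } else {
        stats::cor(log2(x), log2(y))
      }
    }
  )
  list(similarity = sim, n_pairs = length(x), metric = metric)
}
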