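#' BED and bedGraph I/O helpers
#'
#' Minimal readers/writers for the interval formats used by the package:
#' 0-based half-open BED (3+ columns) and bedGraph for occupancy profiles.
#'
#' @param x A tibble with columns `chrom`, `start`, `end` (BED) plus any of
#'   `name`, `score`, `strand`.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE, progress = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(first))]
  readr::read_tsv(path, col_names = nm, show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname write_bed
#' @param profile A normalized `occupancy_profile`.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "occupancy_profile"), isTRUE(profile$normalized))
  rows <- list()
  for (chrom in names(profile$density)) {
    d <- profile$density[[chrom]]
    d[is.na(d)] <- 0
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    rows[[chrom]] <- tibble::tibble(chrom = chrom, start = starts[keep],
                                    end = ends[keep], value = r$values[keep])
  }
  readr::write_tsv(dplyr::bind_rows(rows), path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Write genomes as FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read/write expression tables (gene_id, tpm TSV)
#'
#' @param table Tibble with `gene_id` and `tpm`.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  readr::write_tsv(table[, c("gene_id", "tpm")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, col_types = "cd", progress = FALSE)
}
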