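#' Evolutionary parameters for the clade generator
#'
#' Noise model under which descendant genomes are generated from a common
#' reference: per-site Poisson substitutions, Poisson indels with a geometric
#' length distribution, and an exponential-hazard loss process that deletes
#' whole tiles of sequence (emulating the large-scale turnover that makes
#' unconstrained genomic segments lose homology over time). Segment loss can
#' run at different hazards in accessible vs inaccessible chromatin, the
#' contrast at the heart of the accessible-sequence retention analysis.
#'
#' Defaults are in the range typically quoted for neutral metazoan sequence:
#' around 2e-3 substitutions/site/Myr, an order of magnitude fewer indel
#' events, and a loss hazard of 5e-3/Myr (about 60% of segments retained after
#' 100 Myrs; mammal-like intergenic sequence behaves more like 1.2e-2, about
#' 30% retained).
#'
#' @param sub_rate Substitutions per site per Myr.
#' @param indel_rate Indel events per site per Myr.
#' @param loss_rate Per-Myr hazard of tile loss. Either a single number or a
#'   named vector with any of `default`, `accessible`, `inaccessible` to make
#'   loss chromatin-class specific.
#' @param indel_geom_p Geometric parameter of the indel length distribution
#'   (lengths `rgeom(p) + 1`, capped).
#' @param indel_max_len Indel length cap in bp.
#' @param loss_tile_bp Tile size of the loss process in bp. Tiles are large
#'   relative to the 75 bp sampling segments so that the fraction of segments
#'   retaining homology tracks the surviving-sequence fraction.
#' @return An `evol_params` list.
#' @export
evol_params <- function(sub_rate = 0.002, indel_rate = 2e-4,
                        loss_rate = 0.005, indel_geom_p = 0.3,
                        indel_max_len = 50L, loss_tile_bp = 2000L) {
  lr <- loss_rate
  if (is.null(names(lr))) lr <- c(default = unname(lr[1L]))
  if (!"default" %in% names(lr)) lr <- c(lr, default = unname(lr[1L]))
  stopifnot(sub_rate >= 0, indel_rate >= 0, all(lr >= 0),
            indel_geom_p > 0, indel_geom_p < 1, indel_max_len >= 1,
            loss_tile_bp >= 100)
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 loss_rate = lr, indel_geom_p = indel_geom_p,
                 indel_max_len = as.integer(indel_max_len),
                 loss_tile_bp = as.integer(loss_tile_bp)),
            class = "evol_params")
}

random_genome <- function(length, gc = 0.41, chrom = "chr1") {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- Biostrings::DNAStringSet(paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  names(seqs) <- chrom
  seqs
}

# annotations on a single-chromosome reference: genes, 2 kb upstream promoters,
# intergenic space split into accessible / inaccessible tiles
make_annotations <- function(chrom, length, n_genes, accessible_frac = 0.3,
                             gene_len = 1500L, tile = 1000L) {
  if (n_genes > 0L) {
    slot <- floor(length / n_genes)
    starts <- as.integer((seq_len(n_genes) - 1L) * slot +
                           sample.int(max(1L, slot - gene_len - 2000L), n_genes,
                                      replace = TRUE) + 2000L)
    genes <- tibble::tibble(chrom = chrom, start = starts,
                            end = pmin.int(starts + gene_len, length),
                            gene_id = sprintf("g%04d", seq_len(n_genes)),
                            strand = "+")
    promoters <- tibble::tibble(chrom = chrom,
                                start = pmax.int(genes$start - 2000L, 0L),
                                end = genes$start, gene_id = genes$gene_id)
  } else {
    genes <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), gene_id = character(),
                            strand = character())
    promoters <- genes[, c("chrom", "start", "end", "gene_id")]
  }
  # intergenic complement
  occ <- IRanges::reduce(IRanges::IRanges(c(genes$start, promoters$start) + 1L,
                                          c(genes$end, promoters$end)))
  inter <- IRanges::setdiff(IRanges::IRanges(1L, length), occ)
  pieces <- tibble::tibble(start = IRanges::start(inter) - 1L,
                           end = IRanges::end(inter))
  tiles <- pieces |>
    purrr::pmap_dfr(function(start, end) {
      s <- seq.int(start, end - 1L, by = tile)
      tibble::tibble(start = s, end = pmin.int(s + tile, end))
    }) |>
    dplyr::filter(.data$end - .data$start >= 200L)
  acc <- stats::runif(nrow(tiles)) < accessible_frac
  list(
    genes = genes, promoters = promoters,
    accessible = tibble::tibble(chrom = chrom, start = tiles$start[acc],
                                end = tiles$end[acc]),
    inaccessible = tibble::tibble(chrom = chrom, start = tiles$start[!acc],
                                  end = tiles$end[!acc])
  )
}

#' Generate a synthetic clade of genomes with ground-truth chain maps
#'
#' Produces a random reference genome, annotations (genes, 2 kb upstream
#' promoters, accessible/inaccessible intergenic tiles) and one descendant
#' genome per entry of `species_times`, each evolved independently along its
#' branch by tile-loss, indels and substitutions (see [evol_params()]). For
#' every descendant, the exact block correspondence between reference and
#' descendant coordinates is recorded as a ground-truth [chain_map()], so
#' every downstream coordinate-lifting operation can be validated against the
#' generating history.
#'
#' @param reference_length Reference genome length in bp (>= 10 kb).
#' @param species_times Named numeric vector: species name -> divergence time
#'   in Myrs.
#' @param params An [evol_params()].
#' @param n_genes Number of genes to annotate (default scaled to 1 per 10 kb).
#' @param accessible_frac Fraction of intergenic tiles labelled accessible.
#' @param gc Reference GC content.
#' @param reference Optional single-sequence `DNAStringSet` to evolve from
#'   (e.g. a genome with implanted motifs); a random genome of
#'   `reference_length` bp is generated when `NULL`.
#' @return An object of class `synthetic_clade`: list with `reference`
#'   (DNAStringSet), `descendants` (named list of DNAStringSet), `times`,
#'   `chains` (named list of ground-truth [chain_map()]s), `annotations` and
#'   `params`.
#' @examples
#' set.seed(1)
#' clade <- evolve_clade(20000, c(near = 5, far = 60))
#' clade$chains$near
#' @export
evolve_clade <- function(reference_length, species_times,
                         params = evol_params(), n_genes = NULL,
                         accessible_frac = 0.3, gc = 0.41, reference = NULL) {
  if (is.null(reference)) {
    if (reference_length < 10000) {
      stop_netdecay("reference_length must be at least 10 kb")
    }
    reference <- random_genome(reference_length, gc = gc, chrom = "chr1")
  } else {
    stopifnot(inherits(reference, "DNAStringSet"), length(reference) == 1L)
    reference_length <- Biostrings::width(reference)[1L]
  }
  stopifnot(length(species_times) > 0, all(species_times >= 0),
            !is.null(names(species_times)), inherits(params, "evol_params"))
  chrom <- names(reference)[1L]
  if (is.null(n_genes)) n_genes <- max(3L, reference_length %/% 10000L)
  ann <- make_annotations(chrom, reference_length, n_genes, accessible_frac)
  descendants <- chains <- stats::setNames(vector("list", length(species_times)),
                                           names(species_times))
  for (sp in names(species_times)) {
    ev <- evolve_branch(reference, species_times[[sp]], params, ann)
    descendants[[sp]] <- ev$genome
    chains[[sp]] <- ev$chain
  }
  structure(list(reference = reference, descendants = descendants,
                 times = species_times, chains = chains,
                 annotations = ann, params = params),
            class = "synthetic_clade")
}

#' @export
print.synthetic_clade <- function(x, ...) {
  cat(sprintf("<synthetic_clade> reference %s bp, %d descendant(s): %s\n",
              format(sum(Biostrings::width(x$reference)), big.mark = ","),
              length(x$descendants),
              paste(sprintf("%s (%g Myrs)", names(x$times), x$times),
                    collapse = ", ")))
  invisible(x)
}

# evolve one branch: returns descendant genome + ground-truth chain
evolve_branch <- function(reference, t_myr, params, annotations) {
  chrom <- names(reference)[1L]
  L <- Biostrings::width(reference)[1L]
  base <- strsplit(as.character(reference[[1L]]), "")[[1L]]

  # substitutions: Poisson positions with replacement, so repeated hits give
  # natural back-substitution behaviour. Each event shifts the base by 1-3
  # positions in the alphabet cycle (uniform over the three non-identity
  # shifts); multiple hits compose additively mod 4, so a position hit twice
  # can revert to its original base.
  n_sub <- stats::rpois(1L, params$sub_rate * t_myr * L)
  if (n_sub > 0L) {
    alphabet4 <- c("A", "C", "G", "T")
    pos <- sample.int(L, n_sub, replace = TRUE)
    shift <- sample.int(3L, n_sub, replace = TRUE)
    total <- rowsum(shift, pos)
    upos <- as.integer(rownames(total))
    code <- match(base[upos], alphabet4)
    base[upos] <- alphabet4[((code - 1L + total[, 1L]) %% 4L) + 1L]
  }

  # tile-loss process, chromatin-class-specific hazard
  tile <- params$loss_tile_bp
  tile_starts <- seq.int(0L, L - 1L, by = tile)
  tile_ends <- pmin.int(tile_starts + tile, L)
  hz <- rep(params$loss_rate[["default"]], length(tile_starts))
  mid <- (tile_starts + tile_ends) %/% 2L
  for (cls in c("accessible", "inaccessible")) {
    if (!cls %in% names(params$loss_rate)) next
    reg <- annotations[[cls]]
    if (is.null(reg) || nrow(reg) == 0L) next
    inreg <- IRanges::overlapsAny(IRanges::IRanges(mid + 1L, mid + 1L),
                                  IRanges::IRanges(reg$start + 1L, reg$end))
    hz[inreg] <- params$loss_rate[[cls]]
  }
  lost <- stats::runif(length(tile_starts)) > exp(-hz * t_myr)
  del <- tibble::tibble(start = tile_starts[lost], end = tile_ends[lost])

  # indels
  n_indel <- stats::rpois(1L, params$indel_rate * t_myr * L)
  ins <- tibble::tibble(pos = integer(), len = integer())
  if (n_indel > 0L) {
    ipos <- sample.int(L, n_indel) - 1L
    ilen <- pmin.int(stats::rgeom(n_indel, params$indel_geom_p) + 1L,
                     params$indel_max_len)
    is_del <- stats::runif(n_indel) < 0.5
    del <- dplyr::bind_rows(del, tibble::tibble(
      start = ipos[is_del], end = pmin.int(ipos[is_del] + ilen[is_del], L)))
    ins <- tibble::tibble(pos = ipos[!is_del], len = ilen[!is_del])
  }

  # merge deletions; drop insertions landing inside deleted sequence
  if (nrow(del) > 0L) {
    dr <- IRanges::reduce(IRanges::IRanges(del$start + 1L, del$end))
    del <- tibble::tibble(start = IRanges::start(dr) - 1L, end = IRanges::end(dr))
    if (nrow(ins) > 0L) {
      inside <- IRanges::overlapsAny(IRanges::IRanges(ins$pos + 1L, ins$pos + 1L),
                                     IRanges::IRanges(del$start + 1L, del$end))
      ins <- ins[!inside, , drop = FALSE]
    }
  }
  ins <- ins[order(ins$pos), , drop = FALSE]

  # aligned runs = complement of deletions
  if (nrow(del) > 0L) {
    runs <- IRanges::setdiff(IRanges::IRanges(1L, L),
                             IRanges::IRanges(del$start + 1L, del$end))
    run_s <- IRanges::start(runs) - 1L; run_e <- IRanges::end(runs)
  } else {
    run_s <- 0L; run_e <- L
  }

  # walk the reference emitting descendant sequence and chain blocks
  n_slots <- 2L * (length(run_s) + nrow(ins)) + 4L
  out_parts <- vector("character", n_slots)
  blocks_rs <- blocks_re <- blocks_qs <- integer(length(run_s) + nrow(ins) + 1L)
  np <- 0L; nb <- 0L
  q_off <- 0L
  alphabet <- c("A", "C", "G", "T")
  ins_len_at <- stats::setNames(ins$len, ins$pos)
  for (ri in seq_along(run_s)) {
    s <- run_s[ri]; e <- run_e[ri]
    cuts <- ins$pos[ins$pos > s & ins$pos < e]
    seg_s <- c(s, cuts); seg_e <- c(cuts, e)
    for (k in seq_along(seg_s)) {
      ss <- seg_s[k]; ee <- seg_e[k]
      if (ee > ss) {
        np <- np + 1L
        out_parts[np] <- paste(base[(ss + 1L):ee], collapse = "")
        nb <- nb + 1L
        blocks_rs[nb] <- ss; blocks_re[nb] <- ee; blocks_qs[nb] <- q_off
        q_off <- q_off + (ee - ss)
      }
      if (k < length(seg_s)) {
        # insertion at the cut between consecutive sub-segments
        ilen <- ins_len_at[[as.character(seg_e[k])]]
        np <- np + 1L
        out_parts[np] <- paste(sample(alphabet, ilen, replace = TRUE),
                               collapse = "")
        q_off <- q_off + ilen
      }
    }
  }
  blocks_rs <- blocks_rs[seq_len(nb)]
  blocks_re <- blocks_re[seq_len(nb)]
  blocks_qs <- blocks_qs[seq_len(nb)]
  genome_str <- paste(out_parts[seq_len(np)], collapse = "")
  qlen <- nchar(genome_str)
  if (qlen == 0L) {
    genome_str <- paste(sample(alphabet, 100L, replace = TRUE), collapse = "")
    qlen <- 100L
    blocks_rs <- blocks_re <- blocks_qs <- integer(0)
  }
  genome <- Biostrings::DNAStringSet(genome_str)
  names(genome) <- chrom
  blocks <- tibble::tibble(
    chain_id = 1L, score = sum(blocks_re - blocks_rs),
    ref_chrom = chrom, ref_start = blocks_rs, ref_end = blocks_re,
    q_chrom = chrom, q_start = blocks_qs,
    q_end = blocks_qs + (blocks_re - blocks_rs), q_strand = "+"
  )
  chain <- chain_map(blocks,
                     stats::setNames(L, chrom),
                     stats::setNames(as.integer(qlen), chrom))
  list(genome = genome, chain = chain)
}
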