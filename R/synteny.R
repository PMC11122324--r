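# Synteny block delineation and breakpoint-region extraction from
# two-species marker orders. A synteny block is a maximal run of at least
# two genes consecutive in both species' orders, independent of gene
# orientation; membership ignores strand, and the block sign is derived
# afterwards from the within-block gene order in the target species.

#' Delineate synteny blocks from two marker orders
#'
#' Finds maximal runs of genes consecutive in both the reference order and
#' the target order (orientation-insensitive). Runs of at least two genes
#' become blocks; genes in no such run are reported as singletons and never
#' form blocks, which guards against breakpoint misidentification by
#' single-gene transpositions.
#'
#' Blocks are indexed `1..n` by reference position; `target_rank` is the
#' block's position along the target chromosome, and `sign` is -1 when the
#' within-block gene order is reversed in the target. For a two-gene block
#' the order of its dual-channel probes determines the sign; if no order
#' information distinguishes it (`target_order` carries none beyond
#' adjacency) the run direction in `target_order` is used as given.
#'
#' @param ref_order Character vector: gene ids in reference-chromosome order.
#' @param target_order Character vector: the same gene set in
#'   target-chromosome order.
#' @return List with `blocks` (data frame: `index`, `first_gene`,
#'   `last_gene`, `n_genes`, `target_rank`, `sign`, and list-column
#'   `member_genes` in reference order) and `singletons` (character vector).
#' @examples
#' delineate_blocks(paste0("g", 1:6), paste0("g", c(1, 2, 5, 6, 3, 4)))
#' @export
delineate_blocks <- function(ref_order, target_order) {
  sdiff <- union(setdiff(ref_order, target_order),
                 setdiff(target_order, ref_order))
  if (length(sdiff) > 0L || length(ref_order) != length(target_order))
    stop(sprintf("ref and target gene sets differ; symmetric difference: %s",
                 paste(sdiff, collapse = ", ")))
  if (anyDuplicated(ref_order)) stop("duplicate gene ids in ref_order")
  n <- length(ref_order)
  ref_idx <- match(target_order, ref_order)    # reference rank at each target position

  # maximal runs along the target where reference ranks step by exactly +-1
  step <- diff(ref_idx)
  run_id <- integer(n)
  run_id[1L] <- 1L
  for (k in seq_len(n - 1L)) {
    contiguous <- abs(step[k]) == 1L &&
      (k == 1L || abs(step[k - 1L]) != 1L || step[k] == step[k - 1L])
    run_id[k + 1L] <- if (contiguous) run_id[k] else run_id[k] + 1L
  }
  runs <- split(seq_len(n), run_id)

  blocks <- list(); singles <- character()
  for (r in runs) {
    if (length(r) >= 2L) blocks[[length(blocks) + 1L]] <- r
    else singles <- c(singles, target_order[r])
  }
  if (length(blocks) == 0L) {
    return(list(
      blocks = data.frame(index = integer(), first_gene = character(),
                          last_gene = character(), n_genes = integer(),
                          target_rank = integer(), sign = integer()),
      singletons = singles
    ))
  }
  # order blocks by reference position of their first member
  ref_start <- vapply(blocks, function(r) min(ref_idx[r]), integer(1))
  ord <- order(ref_start)
  blocks <- blocks[ord]
  tgt_rank <- as.integer(rank(vapply(blocks, min, integer(1))))

  member <- lapply(blocks, function(r) ref_order[sort(ref_idx[r])])
  sign <- vapply(blocks, function(r) {
    if (ref_idx[r[2L]] > ref_idx[r[1L]]) 1L else -1L
  }, integer(1))
  df <- data.frame(
    index = seq_along(blocks),
    first_gene = vapply(member, `[`, character(1), 1L),
    last_gene = vapply(member, function(g) g[length(g)], character(1)),
    n_genes = lengths(member),
    target_rank = tgt_rank,
    sign = sign,
    stringsAsFactors = FALSE
  )
  df$member_genes <- member
  list(blocks = df, singletons = singles)
}

#' Signed permutation of block arrangement in the target species
#'
#' Position `k` of the output holds `sign * index` of the block with
#' `target_rank == k`, i.e. the target species' block arrangement written
#' against the reference indexing — the input format of signed
#' rearrangement analysis.
#'
#' @param blocks Block data frame from [delineate_blocks()].
#' @return Signed integer vector.
#' @export
to_signed_permutation <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0L) stop("no blocks")
  if (!setequal(blocks$target_rank, seq_len(n)))
    stop(sprintf("target ranks must be 1..%d; missing: %s", n,
                 paste(setdiff(seq_len(n), blocks$target_rank), collapse = ", ")))
  out <- integer(n)
  out[blocks$target_rank] <- blocks$sign * blocks$index
  out
}

.roman_ids <- function(n) as.character(utils::as.roman(seq_len(n)))

#' Locate breakpoint regions between adjacent synteny blocks
#'
#' One breakpoint region (BR) per adjacent block pair in reference order:
#' the interval from the end of the last gene of the left block to the
#' start of the first gene of the right block. BRs are labelled with Roman
#' numerals I..N left to right.
#'
#' @param blocks Block data frame from [delineate_blocks()].
#' @param annotation Gene annotation data frame covering all flank genes.
#' @return Data frame: `br_id`, `left_flank_gene`, `right_flank_gene`,
#'   `start`, `end` (0-based half-open), `length`.
#' @export
locate_breakpoint_regions <- function(blocks, annotation) {
  if (nrow(blocks) < 2L) {
    return(data.frame(br_id = character(), left_flank_gene = character(),
                      right_flank_gene = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      stringsAsFactors = FALSE))
  }
  blocks <- blocks[order(blocks$index), , drop = FALSE]
  idx <- match(c(blocks$last_gene, blocks$first_gene), annotation$gene_id)
  if (anyNA(idx)) stop("flank gene missing from annotation")
  n <- nrow(blocks)
  left <- blocks$last_gene[-n]
  right <- blocks$first_gene[-1L]
  start <- annotation$end[match(left, annotation$gene_id)]
  end <- annotation$start[match(right, annotation$gene_id)]
  if (any(end < start)) stop("overlapping flank genes between adjacent blocks")
  if (any(end == start)) stop("abutting flank genes give a zero-length breakpoint region")
  data.frame(
    br_id = .roman_ids(n - 1L),
    left_flank_gene = left,
    right_flank_gene = right,
    start = start, end = end,
    length = end - start,
    stringsAsFactors = FALSE
  )
}

#' Block-level length, gene count, and gene density
#'
#' The block reference interval runs from the start of its first gene to
#' the end of its last gene (gene-anchored; breakpoint regions are excluded
#' from block lengths). Density is genes per 100 kb, reported both at full
#' precision and rounded (half-even) to two decimals.
#'
#' @param blocks Block data frame from [delineate_blocks()].
#' @param annotation Gene annotation data frame.
#' @return Data frame: `index`, `start`, `end`, `length_bp`, `n_genes`,
#'   `density_per_100kb`, `density_rounded`.
#' @export
block_metrics <- function(blocks, annotation) {
  first <- match(blocks$first_gene, annotation$gene_id)
  last <- match(blocks$last_gene, annotation$gene_id)
  if (anyNA(first) || anyNA(last)) stop("block member gene missing from annotation")
  start <- annotation$start[first]
  end <- annotation$end[last]
  len <- end - start
  dens <- ifelse(len > 0, blocks$n_genes / (len / 1e5), 0)
  data.frame(
    index = blocks$index,
    start = start, end = end,
    length_bp = len,
    n_genes = blocks$n_genes,
    density_per_100kb = dens,
    density_rounded = round(dens, 2L),
    stringsAsFactors = FALSE
  )
}

#' Gene and base-pair capture of a set of blocks
#'
#' Sums gene counts and block lengths over a subset of blocks (e.g. the
#' blocks spanned by one inversion) and reports them as fractions of all
#' blocks, quantifying how much of the chromosome an inversion captured.
#'
#' @param block_subset Integer vector of block indices (may be empty).
#' @param blocks Block data frame from [delineate_blocks()].
#' @param annotation Gene annotation data frame.
#' @return List: `n_genes`, `total_bp`, `gene_fraction`, `bp_fraction`.
#' @export
capture_stats <- function(block_subset, blocks, annotation) {
  if (length(block_subset) && !all(block_subset %in% blocks$index))
    stop(sprintf("unknown block index: %s",
                 paste(setdiff(block_subset, blocks$index), collapse = ", ")))
  met <- block_metrics(blocks, annotation)
  sel <- met$index %in% block_subset
  list(
    n_genes = sum(met$n_genes[sel]),
    total_bp = sum(met$length_bp[sel]),
    gene_fraction = sum(met$n_genes[sel]) / sum(met$n_genes),
    bp_fraction = sum(met$length_bp[sel]) / sum(met$length_bp)
  )
}
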