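# Repeat and gene density statistics around breakpoint regions. Counting
# convention throughout: an element belongs to a region iff its start
# coordinate lies in the region (0-based half-open), so an element is never
# counted twice across a tiling.

#' Count elements whose start lies in a region
#'
#' @param elements Data frame with a `start` column (and optionally
#'   `group`).
#' @param region Numeric length-2 vector `c(start, end)`, 0-based half-open.
#' @param group Optional group label to filter `elements$group` by.
#' @return Integer count.
#' @export
count_in_region <- function(elements, region, group = NULL) {
  stopifnot(length(region) == 2L, region[2L] >= region[1L])
  x <- elements
  if (!is.null(group)) x <- x[x$group %in% group, , drop = FALSE]
  sum(x$start >= region[1L] & x$start < region[2L])
}

# total bp of `mask` (data frame with start/end, assumed reduced) that
# overlaps [a, b)
.masked_bp <- function(mask, a, b) {
  if (is.null(mask) || nrow(mask) == 0L) return(0)
  sum(pmax(0, pmin(mask$end, b) - pmax(mask$start, a)))
}

# merge possibly-overlapping intervals into a disjoint set
.reduce_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  df <- df[order(df$start), , drop = FALSE]
  out_s <- df$start[1L]; out_e <- df$end[1L]
  s <- numeric(); e <- numeric()
  for (k in seq_len(nrow(df))[-1L]) {
    if (df$start[k] <= out_e) out_e <- max(out_e, df$end[k])
    else { s <- c(s, out_s); e <- c(e, out_e); out_s <- df$start[k]; out_e <- df$end[k] }
  }
  data.frame(start = c(s, out_s), end = c(e, out_e))
}

#' Poisson enrichment test for a breakpoint region
#'
#' The chromosome is tiled with bins of width equal to the region length,
#' from coordinate 0; the trailing partial bin is excluded. The mean count
#' per bin over whole bins gives the Poisson rate `lambda`; `x` is the
#' observed count in the region, and the reported p-value is the upper
#' tail `P(X >= x)` under `Poisson(lambda)` — the point probability alone
#' would not measure enrichment, so the upper tail is used throughout.
#'
#' With a coding mask, both the rate and the observation are computed on
#' non-coding sequence only: elements whose start falls in coding bp are
#' dropped, and the rate is estimated per non-coding bp and scaled by the
#' region's non-coding width, so an empty mask reproduces the unmasked
#' test exactly.
#'
#' @param region Numeric `c(start, end)` of the breakpoint region.
#' @param elements Repeat (or gene) data frame with `start` (and `group`
#'   if `group` given).
#' @param chrom_length Chromosome length in bp.
#' @param coding_mask Optional data frame of coding intervals
#'   (`start`, `end`), or `NULL`.
#' @param group Optional element group filter.
#' @param region_id Label carried into the result.
#' @return List: `region_id`, `lambda`, `observed`, `p_value`,
#'   `masked_coding`, `n_bins`.
#' @export
poisson_br_test <- function(region, elements, chrom_length,
                            coding_mask = NULL, group = NULL,
                            region_id = NA_character_) {
  stopifnot(length(region) == 2L)
  L <- region[2L] - region[1L]
  if (L <= 0) stop("region length must be > 0")
  if (chrom_length < L) stop("chromosome shorter than one bin")
  if (!is.null(group)) elements <- elements[elements$group %in% group, , drop = FALSE]
  masked <- !is.null(coding_mask) && nrow(coding_mask) > 0L
  mask <- if (masked) .reduce_intervals(coding_mask) else NULL
  if (masked) {
    in_coding <- vapply(elements$start, function(s)
      any(mask$start <= s & s < mask$end), logical(1))
    elements <- elements[!in_coding, , drop = FALSE]
  }
  n_bins <- floor(chrom_length / L)
  span <- n_bins * L
  total <- sum(elements$start >= 0 & elements$start < span)
  if (masked) {
    noncoding_span <- span - .masked_bp(mask, 0, span)
    noncoding_region <- L - .masked_bp(mask, region[1L], region[2L])
    if (noncoding_span <= 0) stop("coding mask covers the entire binned span")
    rate_per_bp <- total / noncoding_span
    lambda <- rate_per_bp * noncoding_region
  } else {
    lambda <- total / n_bins
  }
  x <- count_in_region(elements, region)
  p <- if (x == 0L) 1 else stats::ppois(x - 1, lambda, lower.tail = FALSE)
  list(region_id = region_id, lambda = lambda, observed = as.integer(x),
       p_value = p, masked_coding = masked, n_bins = as.integer(n_bins))
}

#' Element-count profile of a breakpoint region and its 50 kb flanks
#'
#' Bars of width equal to the breakpoint-region length cover the interval
#' from 50 kb upstream of the region to 50 kb downstream of it; the region
#' itself is the central bar. Outermost bars are truncated at the
#' chromosome ends (and at the 50 kb flank limit) and carry their true
#' width for density normalization. `lambda_ref` is the chromosome mean
#' count per full-width bar, the reference line of the profile plot.
#'
#' @param br List or one-row data frame with `start`, `end` (and optionally
#'   `br_id`).
#' @param elements Repeat data frame (with `group` if `group` given).
#' @param chrom_length Chromosome length in bp.
#' @param group Optional element group filter.
#' @param flank Flank width in bp (default 50 kb).
#' @return Data frame: `bar`, `start`, `end`, `width`, `count`, `is_br`,
#'   with attributes `lambda_ref` and `br_id`.
#' @export
neighborhood_profile <- function(br, elements, chrom_length, group = NULL,
                                 flank = 5e4) {
  start <- br$start; end <- br$end
  L <- end - start
  if (L < 1e3) stop("breakpoint region shorter than 1 kb")
  if (!is.null(group)) elements <- elements[elements$group %in% group, , drop = FALSE]

  left_edge <- max(0, start - flank)
  right_edge <- min(chrom_length, end + flank)
  lb_end <- start
  left_bars <- NULL
  while (lb_end > left_edge) {
    lb_start <- max(left_edge, lb_end - L)
    left_bars <- rbind(c(lb_start, lb_end), left_bars)
    lb_end <- lb_start
  }
  rb_start <- end
  right_bars <- NULL
  while (rb_start < right_edge) {
    rb_end <- min(right_edge, rb_start + L)
    right_bars <- rbind(right_bars, c(rb_start, rb_end))
    rb_start <- rb_end
  }
  bars <- rbind(left_bars, c(start, end), right_bars)
  is_br <- seq_len(nrow(bars)) == (if (is.null(left_bars)) 1L else nrow(left_bars) + 1L)
  counts <- vapply(seq_len(nrow(bars)), function(k)
    count_in_region(elements, bars[k, ]), numeric(1))
  n_bins <- floor(chrom_length / L)
  lambda_ref <- sum(elements$start >= 0 & elements$start < n_bins * L) / n_bins
  out <- data.frame(
    bar = seq_len(nrow(bars)),
    start = bars[, 1L], end = bars[, 2L],
    width = bars[, 2L] - bars[, 1L],
    count = as.integer(counts),
    is_br = is_br
  )
  attr(out, "lambda_ref") <- lambda_ref
  attr(out, "br_id") <- if (!is.null(br$br_id)) br$br_id else NA_character_
  out
}

#' One-way ANOVA of gene density across synteny blocks
#'
#' Each block is tiled with `bin_size` bins from its start; trailing
#' partial bins are dropped, genes are assigned to bins by start
#' coordinate, and the per-bin counts are compared across blocks with a
#' classical one-way ANOVA.
#'
#' @param blocks Block metric table from [block_metrics()] (needs `index`,
#'   `start`, `end`) or the block data frame plus `annotation`.
#' @param annotation Gene annotation data frame.
#' @param bin_size Bin width in bp (default 100 kb).
#' @return List: `F`, `p_value`, `bins` (data frame: `block`, `bin_start`,
#'   `count`).
#' @export
gene_density_anova <- function(blocks, annotation, bin_size = 1e5) {
  if (!all(c("start", "end") %in% names(blocks)))
    blocks <- block_metrics(blocks, annotation)
  rows <- list()
  for (k in seq_len(nrow(blocks))) {
    n_bins <- floor((blocks$end[k] - blocks$start[k]) / bin_size)
    if (n_bins < 2L)
      stop(sprintf("block %s yields %d whole bin(s); need >= 2",
                   blocks$index[k], n_bins))
    bin_start <- blocks$start[k] + (seq_len(n_bins) - 1L) * bin_size
    counts <- vapply(bin_start, function(s)
      count_in_region(annotation, c(s, s + bin_size)), numeric(1))
    rows[[k]] <- data.frame(block = blocks$index[k], bin_start = bin_start,
                            count = counts)
  }
  bins <- do.call(rbind, rows)
  fit <- stats::aov(count ~ factor(block), data = bins)
  s <- summary(fit)[[1L]]
  Fval <- s[["F value"]][1L]
  pval <- s[["Pr(>F)"]][1L]
  if (is.nan(Fval) && s[["Sum Sq"]][1L] == 0) {   # zero variance everywhere
    Fval <- 0
    pval <- 1
  }
  list(F = Fval, p_value = pval, bins = bins)
}
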