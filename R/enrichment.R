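# Term enrichment for gene lists from rearranged synteny blocks:
# hypergeometric upper-tail test per term, Benjamini-Hochberg and
# Bonferroni adjustment, fold enrichment and odds ratio. Terms are flat
# labels (a gene-to-term table is the input); no ontology-graph
# propagation is performed.

#' Adjust p-values (Benjamini-Hochberg and Bonferroni)
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return List with `fdr_bh` and `bonferroni` vectors, in input order.
#' @export
adjust_pvalues <- function(p_values) {
  if (length(p_values) < 1L) stop("need at least one p-value")
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  list(
    fdr_bh = stats::p.adjust(p_values, method = "BH"),
    bonferroni = stats::p.adjust(p_values, method = "bonferroni")
  )
}

#' Hypergeometric term enrichment of a gene list
#'
#' For every term annotated to at least one list gene, computes the
#' hypergeometric upper-tail probability of drawing `k` or more
#' term-annotated genes in a list of size `n` from a universe of `N` genes
#' of which `K` carry the term, alongside BH and Bonferroni adjustments
#' (over all tested terms), fold enrichment `(k/n)/(K/N)`, and the odds
#' ratio `k * ((N-K)-(n-k)) / ((n-k) * (K-k))`. The odds ratio is reported
#' as `Inf` when every term gene (or every non-list slot) is captured —
#' no continuity correction is applied, so perfect capture prints as
#' infinity rather than a finite shrunk value.
#'
#' @param gene_list Character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param term_table Data frame with `gene_id`, `term_id` and optionally
#'   `term_name`, `domain`.
#' @param universe Character vector: all genes eligible for the draw.
#' @param p_cutoff Only results with `p < p_cutoff` are returned
#'   (default 0.05); `NULL` disables filtering. Adjusted values are always
#'   computed over all tested terms before filtering.
#' @return Data frame sorted by p: `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `p`, `fdr_bh`, `bonferroni`, `fold`, `odds_ratio`.
#' @export
enrich <- function(gene_list, term_table, universe, p_cutoff = 0.05) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop(sprintf("gene(s) outside the universe: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")))
  tt <- term_table[term_table$gene_id %in% universe, , drop = FALSE]
  if (!"term_name" %in% names(tt)) tt$term_name <- tt$term_id
  N <- length(universe)
  n <- length(gene_list)

  by_term <- split(tt, tt$term_id)
  rows <- lapply(by_term, function(d) {
    genes <- unique(d$gene_id)
    K <- length(genes)
    k <- sum(gene_list %in% genes)
    if (k < 1L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- (k / n) / (K / N)
    or <- (k * ((N - K) - (n - k))) / ((n - k) * (K - k))
    data.frame(term_id = d$term_id[1L], term_name = d$term_name[1L],
               k = k, n = n, K = K, N = N, p = p,
               fold = fold, odds_ratio = or, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), fdr_bh = numeric(),
                      bonferroni = numeric(), fold = numeric(),
                      odds_ratio = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  adj <- adjust_pvalues(res$p)
  res$fdr_bh <- adj$fdr_bh
  res$bonferroni <- adj$bonferroni
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  if (!is.null(p_cutoff)) res <- res[res$p < p_cutoff, , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term_id", "term_name", "k", "n", "K", "N", "p", "fdr_bh",
          "bonferroni", "fold", "odds_ratio")]
}
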