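# Ancestral-arrangement inference: each breakpoint region's flanking gene
# adjacency in the two ingroup species is compared against the same gene
# pairs in outgroup genomes. The arrangement matching the outgroups is
# called ancestral; contradictory outgroups leave the call undetermined
# (no majority vote between conflicting outgroups).

.adjacency_states <- c("adjacent_same_order", "adjacent_other_order",
                       "not_adjacent", "unresolved")

.norm_pair <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "|")
}

#' Read an outgroup adjacency table
#'
#' TSV with header and columns `species`, `gene_a`, `gene_b`, `state`,
#' where state is one of `adjacent_same_order`, `adjacent_other_order`,
#' `not_adjacent`, `unresolved` (the latter covering scaffold breaks and
#' missing orthologs). Gene pairs are unordered; relative order is encoded
#' in the state against the alphabetically sorted pair.
#'
#' @param path TSV path.
#' @return Data frame with a normalized `pair` key column added.
#' @export
read_adjacency_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "gene_a", "gene_b", "state")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("adjacency table missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(tab$state), .adjacency_states)
  if (length(bad))
    stop(sprintf("unknown adjacency state(s): %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(.adjacency_states, collapse = ", ")))
  tab$pair <- .norm_pair(tab$gene_a, tab$gene_b)
  tab
}

#' Classify one breakpoint region as ancestral in ingroup A or B
#'
#' An outgroup species supports ingroup A when it shows A's diagnostic
#' adjacency (same unordered gene pair, same adjacency state; gene
#' orientation is ignored since probe orientation in the target species is
#' unknown). The call is `a_ancestral` when at least `min_support`
#' outgroups match A and none match B, symmetrically for `b_ancestral`,
#' and `undetermined` otherwise (including conflicting support).
#' `unresolved` observations never influence a call.
#'
#' @param br_id Breakpoint region label carried into the result.
#' @param ingroup_a,ingroup_b One-row data frames (or lists) with
#'   `gene_a`, `gene_b`, `state`: the diagnostic adjacency of each ingroup
#'   at this breakpoint region.
#' @param outgroup_obs Data frame of outgroup observations (`species`,
#'   `gene_a`, `gene_b`, `state`).
#' @param min_support Minimum number of matching outgroups (default 1).
#' @return List: `br_id`, `call` in `{a_ancestral, b_ancestral,
#'   undetermined}`, `n_support_a`, `n_support_b`, `reason`.
#' @export
classify_br_ancestry <- function(br_id, ingroup_a, ingroup_b, outgroup_obs,
                                 min_support = 1L) {
  if (nrow(outgroup_obs) == 0L)
    stop("need at least one outgroup observation")
  obs <- outgroup_obs
  if (!"pair" %in% names(obs)) obs$pair <- .norm_pair(obs$gene_a, obs$gene_b)
  obs <- obs[obs$state != "unresolved", , drop = FALSE]

  key_a <- paste(.norm_pair(ingroup_a$gene_a, ingroup_a$gene_b), ingroup_a$state)
  key_b <- paste(.norm_pair(ingroup_b$gene_a, ingroup_b$gene_b), ingroup_b$state)
  match_a <- unique(obs$species[paste(obs$pair, obs$state) == key_a])
  match_b <- unique(obs$species[paste(obs$pair, obs$state) == key_b])

  na <- length(match_a); nb <- length(match_b)
  call <- "undetermined"
  reason <- NULL
  if (nrow(obs) == 0L) {
    reason <- "no_data"
  } else if (na >= min_support && nb == 0L) {
    call <- "a_ancestral"
  } else if (nb >= min_support && na == 0L) {
    call <- "b_ancestral"
  } else if (na > 0L && nb > 0L) {
    reason <- "conflicting_outgroups"
  } else {
    reason <- "insufficient_support"
  }
  list(br_id = br_id, call = call, n_support_a = na, n_support_b = nb,
       reason = reason)
}

#' Chromosome-level ancestry verdict
#'
#' Majority over the determined per-BR calls; undetermined regions are
#' reported but never overridden. A split among determined calls gives
#' verdict `mixed`; no determined call gives `undetermined`.
#'
#' @param per_br_calls List of results from [classify_br_ancestry()].
#' @return List: `verdict` in `{a_ancestral, b_ancestral, mixed,
#'   undetermined}`, `n_a`, `n_b`, `n_undetermined`, `detail` (data frame).
#' @export
summarize_ancestry <- function(per_br_calls) {
  if (length(per_br_calls) == 0L) stop("need at least one breakpoint-region call")
  calls <- vapply(per_br_calls, `[[`, character(1), "call")
  n_a <- sum(calls == "a_ancestral")
  n_b <- sum(calls == "b_ancestral")
  n_u <- sum(calls == "undetermined")
  verdict <- if (n_a == 0L && n_b == 0L) "undetermined"
             else if (n_a > 0L && n_b > 0L) "mixed"
             else if (n_a > 0L) "a_ancestral" else "b_ancestral"
  detail <- data.frame(
    br_id = vapply(per_br_calls, `[[`, character(1), "br_id"),
    call = calls,
    n_support_a = vapply(per_br_calls, `[[`, integer(1), "n_support_a"),
    n_support_b = vapply(per_br_calls, `[[`, integer(1), "n_support_b"),
    stringsAsFactors = FALSE
  )
  list(verdict = verdict, n_a = n_a, n_b = n_b, n_undetermined = n_u,
       detail = detail)
}
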