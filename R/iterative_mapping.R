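# Iterative FISH marker-selection loop: starting from a sparse scaffold of
# markers, classify each localized marker as collinear or translocated,
# open a candidate interval across every classification boundary, and keep
# probing genes inside open intervals until no mappable marker remains
# between the flanks.

#' Classify localized markers as collinear or translocated
#'
#' Orders markers by reference coordinate and finds the longest
#' non-decreasing (or non-increasing, whichever is longer; ties favour
#' non-decreasing) subsequence of target zone ranks — the collinear
#' backbone. Markers outside the backbone have moved relative to the
#' reference and are called translocated. Zone ties join the backbone
#' (zones are coarse cytogenetic bins, so equal zones carry no order
#' signal).
#'
#' @param localizations Marker data frame with `gene_id`, `ref_coord`, and
#'   `zone_rank` (as from [read_marker_table()] or [simulate_fish()]).
#' @return The input with a `status` column (`"collinear"` /
#'   `"translocated"`), rows ordered by `ref_coord`.
#' @export
classify_markers <- function(localizations) {
  if (nrow(localizations) < 2L) stop("need at least 2 localized markers")
  loc <- localizations[order(localizations$ref_coord), , drop = FALSE]
  z <- loc$zone_rank
  if (length(unique(z)) == 1L)
    stop("all markers fall in one zone: collinearity is indeterminate")

  longest_monotone <- function(v) {       # indices of longest non-decreasing subsequence
    n <- length(v)
    len <- rep(1L, n); prev <- rep(0L, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      if (v[j] <= v[i] && len[j] + 1L > len[i]) { len[i] <- len[j] + 1L; prev[i] <- j }
    }
    i <- which.max(len)
    out <- integer(0)
    while (i != 0L) { out <- c(i, out); i <- prev[i] }
    out
  }
  up <- longest_monotone(z)
  down <- longest_monotone(-z)
  backbone <- if (length(down) > length(up)) down else up
  loc$status <- "translocated"
  loc$status[backbone] <- "collinear"
  rownames(loc) <- NULL
  loc
}

#' Derive candidate breakpoint intervals from classified markers
#'
#' A candidate interval opens across every pair of consecutive (by
#' reference coordinate) localized markers whose collinear/translocated
#' classification differs. Interval bounds are the end of the left
#' bounding gene and the start of the right bounding gene, so a fully
#' refined interval equals the intergenic gap at the breakpoint.
#'
#' @param classified Output of [classify_markers()].
#' @param annotation Gene annotation data frame.
#' @param round_opened Round index recorded on the intervals.
#' @return Data frame: `hypothesis_id`, `left_gene`, `right_gene`, `start`,
#'   `end`, `width`, `round_opened`.
#' @export
candidate_intervals <- function(classified, annotation, round_opened = NA_integer_) {
  cl <- classified[order(classified$ref_coord), , drop = FALSE]
  n <- nrow(cl)
  boundary <- which(cl$status[-n] != cl$status[-1L])
  if (length(boundary) == 0L)
    return(data.frame(hypothesis_id = character(), left_gene = character(),
                      right_gene = character(), start = numeric(),
                      end = numeric(), width = numeric(),
                      round_opened = integer(), stringsAsFactors = FALSE))
  left <- cl$gene_id[boundary]
  right <- cl$gene_id[boundary + 1L]
  start <- annotation$end[match(left, annotation$gene_id)]
  end <- annotation$start[match(right, annotation$gene_id)]
  if (anyNA(start) || anyNA(end)) stop("bounding gene missing from annotation")
  data.frame(
    hypothesis_id = paste0("BRH", seq_along(boundary)),
    left_gene = left, right_gene = right,
    start = start, end = end, width = end - start,
    round_opened = round_opened,
    stringsAsFactors = FALSE
  )
}

#' Propose the next round of FISH markers
#'
#' For each open candidate interval, picks up to `k` available genes
#' nearest to the `k` interior quantile points `i / (k + 1)` of the
#' interval (a k-ary generalization of bisection). Genes are located by
#' reference midpoint and must lie strictly inside the interval. An empty
#' proposal means no mappable marker remains inside any open interval —
#' the loop's stop condition.
#'
#' @param candidates Data frame from [candidate_intervals()].
#' @param available_genes Character vector of gene ids not yet mapped and
#'   not flagged unmappable.
#' @param annotation Gene annotation data frame.
#' @param k Markers per interval per round (default 3, matching a three-
#'   to-four probes-per-experiment design).
#' @return Character vector of proposed gene ids (possibly empty).
#' @export
propose_next_markers <- function(candidates, available_genes, annotation, k = 3L) {
  if (nrow(candidates) == 0L || length(available_genes) == 0L) return(character())
  ann <- annotation[annotation$gene_id %in% available_genes, , drop = FALSE]
  mid <- gene_midpoint(ann)
  picks <- character()
  for (r in seq_len(nrow(candidates))) {
    inside <- which(mid > candidates$start[r] & mid < candidates$end[r])
    if (length(inside) == 0L) next
    q <- candidates$start[r] +
      seq_len(k) / (k + 1) * (candidates$end[r] - candidates$start[r])
    sel <- unique(vapply(q, function(point)
      inside[which.min(abs(mid[inside] - point))], integer(1)))
    picks <- c(picks, ann$gene_id[sel])
  }
  unique(picks)
}

#' Run an iterative mapping campaign on a simulated chromosome
#'
#' Emulates the full marker-selection loop against a simulated chromosome
#' with hidden ground truth: a first round of markers spaced roughly
#' `round1_spacing` apart is localized by simulated FISH, markers are
#' classified, candidate breakpoint intervals open at classification
#' boundaries, and each subsequent round probes up to `k` genes per open
#' interval until no available gene lies inside any interval. Probes that
#' fail to localize (per-gene mappability drawn by the simulator) are
#' flagged and never proposed again. Deterministic given `seed`.
#'
#' @param sim Simulated chromosome from [simulate_chromosome()].
#' @param k Markers per interval per round.
#' @param seed Integer seed for the FISH noise stream.
#' @param round1_spacing Spacing of the first-round marker scaffold in bp.
#' @param max_rounds Guard against non-convergence.
#' @return List: `final_intervals` (data frame), `log` (per-round data
#'   frame: round, n_probed, n_localized, n_intervals, total_width),
#'   `localizations` (all marker localizations).
#' @export
run_campaign <- function(sim, k = 3L, seed = 1L, round1_spacing = 1e6,
                         max_rounds = 25L) {
  ann <- sim$genes
  mid <- gene_midpoint(ann)
  set.seed(seed)

  # round 1: scaffold of markers on a regular grid, nearest gene to each
  # point; short chromosomes get at least a ten-point scaffold
  spacing <- min(round1_spacing, sim$config$chrom_length / 10)
  grid <- seq(spacing / 2, sim$config$chrom_length, by = spacing)
  scaffold <- unique(vapply(grid, function(g) which.min(abs(mid - g)), integer(1)))
  probes <- ann$gene_id[scaffold]

  flagged <- character()       # probed but unmappable
  localized <- NULL
  log <- NULL
  intervals <- NULL
  for (round in seq_len(max_rounds)) {
    obs <- simulate_fish(sim, probes, round = round)
    failed <- setdiff(probes, obs$gene_id)
    flagged <- union(flagged, failed)
    localized <- rbind(localized, obs)
    cl <- classify_markers(localized)
    intervals <- candidate_intervals(cl, ann, round_opened = round)
    log <- rbind(log, data.frame(
      round = round, n_probed = length(probes), n_localized = nrow(obs),
      n_intervals = nrow(intervals), total_width = sum(intervals$width)
    ))
    available <- setdiff(ann$gene_id, union(localized$gene_id, flagged))
    probes <- propose_next_markers(intervals, available, ann, k = k)
    if (length(probes) == 0L) break
    if (round == max_rounds)
      stop(sprintf("campaign did not converge in %d rounds (%d open proposals)",
                   max_rounds, length(probes)))
  }
  list(final_intervals = intervals, log = log, localizations = localized)
}
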