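# Synthetic chromosome generator: genes packed into synteny blocks
# separated by gene-free breakpoint gaps, per-group Poisson repeat tracks
# with optional enrichment inside the true breakpoint regions, a planted
# block-level reversal scenario defining the target species, and
# simulated FISH localization with zone-level noise and per-gene
# mappability. All randomness flows from the single config seed.

#' Build a simulation configuration
#'
#' Defaults describe a mosquito-X-like chromosome; [paper_scale_config()]
#' is the preset with the five-block structure used throughout.
#'
#' @param block_lengths Block lengths in bp (first-gene start to last-gene
#'   end).
#' @param block_genes Gene count per block.
#' @param br_lengths Breakpoint-gap lengths in bp (one fewer than blocks).
#' @param margin Gene-free bp before the first and after the last block.
#' @param gene_length_mean,gene_length_sd Gene length distribution (bp,
#'   normal truncated at 200 bp).
#' @param repeat_rates Named expected element counts per 100 kb for groups
#'   `retrotransposon`, `dna_transposon`, `unknown_te`, `simple_repeat`.
#' @param planted_scenario List of `c(i, j)` block-level reversals applied
#'   to the identity arrangement to produce the target species.
#' @param br_repeat_multiplier Repeat-rate multiplier inside true
#'   breakpoint gaps (>= 1; 1 = no enrichment).
#' @param zone_count Number of equal-width cytogenetic zones on the target
#'   chromosome.
#' @param localization_noise Probability that a FISH localization is
#'   perturbed by one zone.
#' @param unmappable_prob Per-gene probability that a probe never
#'   localizes.
#' @param seed Integer seed driving all randomness.
#' @return A `simulation_config` list; chromosome length is derived as
#'   margins + blocks + gaps.
#' @export
simulation_config <- function(block_lengths = c(12e5, 5e5, 2e6, 8e5, 1e6),
                              block_genes = c(90, 40, 150, 60, 80),
                              br_lengths = rep(1e4, length(block_lengths) - 1L),
                              margin = c(2e4, 2e4),
                              gene_length_mean = 3000,
                              gene_length_sd = 1000,
                              repeat_rates = c(retrotransposon = 2,
                                               dna_transposon = 20,
                                               unknown_te = 5,
                                               simple_repeat = 40),
                              planted_scenario = list(c(3L, 3L), c(2L, 4L)),
                              br_repeat_multiplier = 1,
                              zone_count = 39L,
                              localization_noise = 0,
                              unmappable_prob = 0,
                              seed = 1L) {
  stopifnot(length(block_genes) == length(block_lengths),
            length(br_lengths) == length(block_lengths) - 1L,
            all(block_lengths > 0), all(block_genes >= 0),
            all(br_lengths > 0), br_repeat_multiplier >= 1,
            localization_noise >= 0, localization_noise <= 1,
            unmappable_prob >= 0, unmappable_prob <= 1,
            zone_count >= 2L)
  if (any(!names(repeat_rates) %in% c("retrotransposon", "dna_transposon",
                                      "unknown_te", "simple_repeat")) ||
      any(repeat_rates < 0))
    stop("repeat_rates must be non-negative and named by the four groups")
  cfg <- list(
    block_lengths = block_lengths, block_genes = block_genes,
    br_lengths = br_lengths, margin = margin,
    gene_length_mean = gene_length_mean, gene_length_sd = gene_length_sd,
    repeat_rates = repeat_rates, planted_scenario = planted_scenario,
    br_repeat_multiplier = br_repeat_multiplier, zone_count = as.integer(zone_count),
    localization_noise = localization_noise, unmappable_prob = unmappable_prob,
    seed = as.integer(seed),
    chrom = "X",
    chrom_length = sum(margin) + sum(block_lengths) + sum(br_lengths)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' The five-block study-scale preset
#'
#' Five blocks of 1,458,895 / 526,550 / 10,348,225 / 2,148,753 / 3,273,690
#' bp carrying 122 / 42 / 722 / 137 / 199 genes (17,756,113 bp of blocks,
#' 1,222 genes), breakpoint gaps of 9 / 8 / 12 / 7 kb, 20 kb terminal
#' margins (17,832,113 bp chromosome), and a planted nested two-inversion
#' scenario turning the identity arrangement into 1, -4, 3, -2, 5.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @export
paper_scale_config <- function(...) {
  args <- list(
    block_lengths = c(1458895, 526550, 10348225, 2148753, 3273690),
    block_genes = c(122L, 42L, 722L, 137L, 199L),
    br_lengths = c(9000, 8000, 12000, 7000),
    margin = c(2e4, 2e4),
    planted_scenario = list(c(3L, 3L), c(2L, 4L))
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

.repeat_labels <- list(
  retrotransposon = c("LTR/Gypsy", "LTR/Copia", "LINE"),
  dna_transposon = c("TIR/CACTA", "TIR/Mutator", "TIR/PIF_Harbinger",
                     "TIR/Tc1_Mariner", "TIR/hAT", "Helitron"),
  unknown_te = "Repeat_region",
  simple_repeat = c("Simple_repeat", "Low_complexity")
)

#' Generate the reference chromosome of a simulation
#'
#' Genes are packed without overlap into the block intervals (the first
#' gene starts at the block start and the last ends at the block end, so
#' block metrics recover the configured lengths exactly); breakpoint gaps
#' and margins carry no genes. Repeats are placed by independent per-group
#' Poisson processes, with the group rate multiplied by
#' `br_repeat_multiplier` inside the true breakpoint gaps. Fully
#' deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return List: `genes` (annotation data frame), `repeats` (repeat data
#'   frame), `truth` (block gene ranges and reference intervals, true
#'   breakpoint-gap intervals, planted scenario, per-gene mappability).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  B <- length(config$block_lengths)

  block_start <- config$margin[1L] +
    cumsum(c(0, config$block_lengths[-B] + config$br_lengths))
  block_end <- block_start + config$block_lengths
  br_start <- block_end[-B]
  br_end <- br_start + config$br_lengths

  genes <- list()
  gid <- 0L
  for (b in seq_len(B)) {
    nb <- config$block_genes[b]
    if (nb == 0L) next
    len <- pmax(200, round(stats::rnorm(nb, config$gene_length_mean,
                                        config$gene_length_sd)))
    if (sum(len) > config$block_lengths[b])
      stop(sprintf("infeasible packing: %d genes (%.0f bp) exceed block %d (%.0f bp)",
                   nb, sum(len), b, config$block_lengths[b]))
    if (nb == 1L) {
      len <- config$block_lengths[b]       # a single gene spans its block
      starts <- block_start[b]
    } else {
      # First gene pinned to the block start and last to the block end, so
      # delineated block intervals recover the configured lengths exactly;
      # interior genes at sorted uniform positions, overlaps resolved by a
      # minimal-displacement sweep (keeps the point process near-uniform at
      # the bin scales used for density statistics).
      lo <- block_start[b] + len[1L]
      hi <- block_end[b] - len[nb]
      starts <- c(block_start[b],
                  sort(floor(stats::runif(nb - 2L, lo, hi))),
                  hi)
      if (nb > 2L) {
        for (i in 2:(nb - 1L))                       # push right off the left neighbour
          starts[i] <- max(starts[i], starts[i - 1L] + len[i - 1L])
        for (i in (nb - 1L):2)                       # pull left off the right neighbour
          starts[i] <- min(starts[i], starts[i + 1L] - len[i])
        if (any(diff(starts) < len[-nb]))
          stop(sprintf("infeasible packing in block %d", b))
      }
    }
    genes[[b]] <- data.frame(
      gene_id = sprintf("G%04d", gid + seq_len(nb)),
      chrom = config$chrom,
      start = starts, end = starts + len,
      strand = sample(c("+", "-"), nb, replace = TRUE),
      block = b,
      stringsAsFactors = FALSE
    )
    gid <- gid + nb
  }
  genes <- if (length(genes)) do.call(rbind, genes)
           else data.frame(gene_id = character(), chrom = character(),
                           start = numeric(), end = numeric(),
                           strand = character(), block = integer(),
                           stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  # Repeat tracks: homogeneous Poisson per group. The baseline process runs
  # over the whole chromosome; extra elements at rate (multiplier - 1) are
  # overlaid inside each BR gap, so the BR rate is exactly rate * multiplier.
  repeats <- list()
  for (grp in names(config$repeat_rates)) {
    rate <- config$repeat_rates[[grp]] / 1e5    # per bp
    n0 <- stats::rpois(1L, rate * config$chrom_length)
    starts <- sort(stats::runif(n0, 0, config$chrom_length))
    if (config$br_repeat_multiplier > 1) {
      extra_rate <- rate * (config$br_repeat_multiplier - 1)
      for (g in seq_len(B - 1L)) {
        ng <- stats::rpois(1L, extra_rate * config$br_lengths[g])
        starts <- c(starts, stats::runif(ng, br_start[g], br_end[g]))
      }
    }
    if (length(starts) == 0L) next
    starts <- floor(sort(starts))
    lens <- pmax(20, round(stats::rlnorm(length(starts), log(300), 0.7)))
    labels <- sample(.repeat_labels[[grp]], length(starts), replace = TRUE)
    repeats[[grp]] <- data.frame(
      chrom = config$chrom, start = starts,
      end = pmin(starts + lens, config$chrom_length),
      family_label = labels, group = grp, stringsAsFactors = FALSE
    )
  }
  repeats <- if (length(repeats)) do.call(rbind, repeats)
             else data.frame(chrom = character(), start = numeric(),
                             end = numeric(), family_label = character(),
                             group = character(), stringsAsFactors = FALSE)
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL

  truth <- list(
    block_start = block_start, block_end = block_end,
    block_genes = split(genes$gene_id, genes$block),
    br_intervals = data.frame(br_id = .roman_ids(B - 1L),
                              start = br_start, end = br_end),
    scenario = config$planted_scenario,
    mappable = stats::setNames(stats::runif(nrow(genes)) >= config$unmappable_prob,
                               genes$gene_id)
  )
  list(genes = genes[, c("gene_id", "chrom", "start", "end", "strand")],
       repeats = repeats, truth = truth)
}

#' Derive the target species' gene order from the planted scenario
#'
#' Applies the block-level reversal scenario to the identity arrangement
#' and expands it to gene level: blocks are concatenated in their new
#' order, with gene order and strand reversed inside inverted blocks.
#' Target coordinates re-use the reference block and gap lengths laid out
#' in the new order, preserving within-block offsets (mirrored under
#' inversion).
#'
#' @param reference Output of [generate_reference()].
#' @param config The [simulation_config()] used to generate it.
#' @return Data frame in target order: `gene_id`, `target_rank`,
#'   `target_start`, `target_end`, `target_strand`, `source_block`.
#' @export
derive_target_species <- function(reference, config) {
  truth <- reference$truth
  B <- length(config$block_lengths)
  arr <- seq_len(B)
  for (step in config$planted_scenario)
    arr <- apply_reversal(arr, step[1L], step[2L])

  genes <- reference$genes
  genes$mid_offset <- NA_real_
  out <- list()
  cursor <- config$margin[1L]
  rank0 <- 0L
  for (pos in seq_len(B)) {
    b <- abs(arr[pos])
    inverted <- arr[pos] < 0L
    ids <- truth$block_genes[[as.character(b)]]
    g <- genes[match(ids, genes$gene_id), , drop = FALSE]
    off_s <- g$start - truth$block_start[b]
    off_e <- g$end - truth$block_start[b]
    L <- config$block_lengths[b]
    if (inverted) {
      ts <- cursor + (L - off_e)
      te <- cursor + (L - off_s)
      strand <- ifelse(g$strand == "+", "-", "+")
      ord <- order(ts)
    } else {
      ts <- cursor + off_s
      te <- cursor + off_e
      strand <- g$strand
      ord <- order(ts)
    }
    out[[pos]] <- data.frame(
      gene_id = g$gene_id[ord],
      target_rank = rank0 + seq_along(ord),
      target_start = ts[ord], target_end = te[ord],
      target_strand = strand[ord],
      source_block = b,
      stringsAsFactors = FALSE
    )
    rank0 <- rank0 + length(ord)
    cursor <- cursor + L + if (pos < B) config$br_lengths[pos] else 0
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a chromosome end to end
#'
#' Convenience wrapper bundling [generate_reference()] and
#' [derive_target_species()] into the object consumed by
#' [run_campaign()] and [simulate_fish()].
#'
#' @param config A [simulation_config()].
#' @return List: `genes`, `repeats`, `truth`, `target`, `config`.
#' @export
simulate_chromosome <- function(config) {
  ref <- generate_reference(config)
  target <- derive_target_species(ref, config)
  list(genes = ref$genes, repeats = ref$repeats, truth = ref$truth,
       target = target, config = config)
}

#' Simulate FISH localization of probes on the target chromosome
#'
#' Each mappable probe reports the equal-width cytogenetic zone of its
#' true target-chromosome midpoint, perturbed by one zone with probability
#' `localization_noise`; unmappable probes (per-gene flags drawn at
#' generation time) are silently omitted, as a failed hybridization
#' produces no signal.
#'
#' @param sim Simulation from [simulate_chromosome()].
#' @param probes Character vector of gene ids to probe (subset of the gene
#'   set).
#' @param round Round index recorded on the localizations.
#' @return Marker localization data frame: `gene_id`, `ref_coord`, `zone`,
#'   `zone_rank`, `round`, `channel`.
#' @export
simulate_fish <- function(sim, probes, round = 1L) {
  cfg <- sim$config
  bad <- setdiff(probes, sim$genes$gene_id)
  if (length(bad))
    stop(sprintf("probe(s) not in gene set: %s", paste(utils::head(bad, 5L), collapse = ", ")))
  probes <- probes[sim$truth$mappable[probes]]
  if (length(probes) == 0L) {
    return(data.frame(gene_id = character(), ref_coord = numeric(),
                      zone = character(), zone_rank = integer(),
                      round = integer(), channel = character(),
                      stringsAsFactors = FALSE))
  }
  tgt <- sim$target[match(probes, sim$target$gene_id), , drop = FALSE]
  mid <- (tgt$target_start + tgt$target_end) / 2
  width <- cfg$chrom_length / cfg$zone_count
  zone_rank <- pmin(cfg$zone_count, pmax(1L, floor(mid / width) + 1L))
  flip <- stats::runif(length(probes)) < cfg$localization_noise
  shift <- ifelse(flip, sample(c(-1L, 1L), length(probes), replace = TRUE), 0L)
  zone_rank <- pmin(cfg$zone_count, pmax(1L, zone_rank + shift))
  ref <- sim$genes[match(probes, sim$genes$gene_id), , drop = FALSE]
  data.frame(
    gene_id = probes,
    ref_coord = gene_midpoint(ref),
    zone = zone_labels(cfg$zone_count)[zone_rank],
    zone_rank = as.integer(zone_rank),
    round = as.integer(round),
    channel = rep(c("dye_a", "dye_b"), length.out = length(probes)),
    stringsAsFactors = FALSE
  )
}

#' Ordered zone labels of the target chromosome
#'
#' @param zone_count Number of zones.
#' @return Character vector `z01 ... zNN` in chromosomal order.
#' @export
zone_labels <- function(zone_count) {
  sprintf("z%02d", seq_len(zone_count))
}
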