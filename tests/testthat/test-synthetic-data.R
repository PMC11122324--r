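test_that("generation is deterministic given the seed", {
  a <- simulate_chromosome(simulation_config(seed = 17L))
  b <- simulate_chromosome(simulation_config(seed = 17L))
  expect_identical(a$genes, b$genes)
  expect_identical(a$repeats, b$repeats)
  expect_identical(a$target, b$target)
  c <- simulate_chromosome(simulation_config(seed = 18L))
  expect_false(identical(a$genes, c$genes))
})

test_that("the study-scale preset emits the configured structure exactly", {
  sim <- simulate_chromosome(paper_scale_config(seed = 2L))
  expect_equal(nrow(sim$genes), 1222L)
  expect_equal(lengths(sim$truth$block_genes, use.names = FALSE),
               c(122L, 42L, 722L, 137L, 199L))
  expect_equal(sim$config$chrom_length, 17832113)
  # genes are disjoint and sorted; blocks span their configured intervals
  expect_true(all(diff(sim$genes$start) > 0))
  expect_true(all(sim$genes$start[-1] >= sim$genes$end[-nrow(sim$genes)]))
  expect_equal(sim$truth$block_end - sim$truth$block_start,
               c(1458895, 526550, 10348225, 2148753, 3273690))
  # no gene inside any breakpoint gap
  for (k in seq_len(nrow(sim$truth$br_intervals))) {
    br <- sim$truth$br_intervals[k, ]
    expect_equal(count_in_region(sim$genes, c(br$start, br$end)), 0L)
  }
})

test_that("zero genes still yields a valid repeat-only chromosome", {
  cfg <- simulation_config(block_genes = rep(0L, 5), seed = 4L)
  sim <- generate_reference(cfg)
  expect_equal(nrow(sim$genes), 0L)
  expect_gt(nrow(sim$repeats), 0L)
})

test_that("the target order conserves genes and applies the planted scenario", {
  sim <- small_sim(seed = 9L)
  expect_setequal(sim$target$gene_id, sim$genes$gene_id)
  expect_equal(nrow(sim$target), nrow(sim$genes))
  # planted {(3,3),(2,4)} on five blocks -> arrangement 1, -4, 3, -2, 5
  expect_equal(unique(sim$target$source_block), c(1L, 4L, 3L, 2L, 5L))

  # empty scenario leaves the order identical
  flat <- simulate_chromosome(simulation_config(planted_scenario = list(),
                                                seed = 9L))
  expect_equal(flat$target$gene_id, flat$genes$gene_id)
  expect_equal(flat$target$target_start, flat$genes$start)

  # round trip: delineation recovers the planted boundaries
  res <- delineate_blocks(sim$genes$gene_id, sim$target$gene_id)
  met <- block_metrics(res$blocks, sim$genes)
  expect_equal(met$start, sim$truth$block_start)
  expect_equal(met$end, sim$truth$block_end)
  expect_equal(to_signed_permutation(res$blocks), c(1L, -4L, 3L, -2L, 5L))
})

test_that("repeat enrichment is planted only inside breakpoint gaps", {
  cfg <- simulation_config(block_lengths = rep(3e5, 5), block_genes = rep(10, 5),
                           br_lengths = rep(2e4, 4),
                           br_repeat_multiplier = 12, seed = 21L)
  sim <- simulate_chromosome(cfg)
  dna <- sim$repeats[sim$repeats$group == "dna_transposon", ]
  br <- sim$truth$br_intervals
  in_br <- sum(vapply(seq_len(nrow(br)), function(k)
    count_in_region(dna, c(br$start[k], br$end[k])), numeric(1)))
  br_bp <- sum(br$end - br$start)
  out_bp <- cfg$chrom_length - br_bp
  rate_in <- in_br / br_bp
  rate_out <- (nrow(dna) - in_br) / out_bp
  expect_gt(rate_in, 5 * rate_out)   # 12x planted, allow sampling noise
})

test_that("simulated FISH reports true zones noise-free and omits unmappable probes", {
  sim <- small_sim(seed = 12L)
  set.seed(1)
  obs <- simulate_fish(sim, sim$genes$gene_id, round = 1L)
  expect_equal(nrow(obs), nrow(sim$genes))
  # zone ranks follow target order (non-decreasing along target ranks)
  ord <- match(obs$gene_id, sim$target$gene_id)
  expect_true(all(diff(obs$zone_rank[order(sim$target$target_rank[ord])]) >= 0))

  none <- simulate_chromosome(simulation_config(unmappable_prob = 1,
                                                seed = 12L))
  set.seed(1)
  expect_equal(nrow(simulate_fish(none, none$genes$gene_id)), 0L)
  expect_error(simulate_fish(sim, "nope"), "not in gene set")
})

test_that("localization noise perturbs close to the configured fraction of zones", {
  noisy <- simulate_chromosome(simulation_config(localization_noise = 0.1,
                                                 seed = 15L))
  clean <- simulate_chromosome(simulation_config(localization_noise = 0,
                                                 seed = 15L))
  expect_identical(noisy$genes, clean$genes)   # noise only affects FISH
  probes <- clean$genes$gene_id
  moved <- replicate(30, {
    o1 <- simulate_fish(noisy, probes)
    o0 <- simulate_fish(clean, probes)
    mean(o1$zone_rank != o0$zone_rank)
  })
  # boundary clamping can only keep a perturbed zone in place, never add moves
  expect_lt(mean(moved), 0.12)
  expect_gt(mean(moved), 0.06)
})
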