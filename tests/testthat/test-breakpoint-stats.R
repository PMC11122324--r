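test_that("elements are counted by start coordinate, once each", {
  el <- data.frame(start = c(-50, 5, 10, 99, 100, 150),
                   group = "dna_transposon")
  expect_equal(count_in_region(el, c(0, 100)), 3L)   # spanning-in element excluded
  expect_equal(count_in_region(el, c(40, 40)), 0L)   # empty region
  expect_equal(count_in_region(el, c(0, 100), group = "simple_repeat"), 0L)
})

test_that("a breakpoint-region repeat inventory sums like a contents table", {
  # 1 CACTA + 1 hAT + 8 Harbinger-MITE + 1 Helitron + 1 Unknown inside the BR
  path <- withr::local_tempfile(fileext = ".bed")
  starts <- seq(1000, by = 500, length.out = 12)
  labels <- c("TIR/CACTA", "TIR/hAT", rep("DNA/DTH_PIF_Harbinger_MITE", 8),
              "Helitron", "Unknown")
  writeLines(sprintf("X\t%d\t%d\t%s", starts, starts + 200, labels), path)
  rep <- read_repeat_bed(path)
  br <- c(500, 8000)
  expect_equal(count_in_region(rep, br, group = c("dna_transposon", "unknown_te")),
               12L)
  expect_equal(count_in_region(rep, br, group = "dna_transposon"), 11L)
  expect_equal(count_in_region(rep, br, group = "unknown_te"), 1L)
})

test_that("the Poisson upper tail matches a hand-summed oracle", {
  # lambda = 2 exactly: 20 elements over 10 whole bins; 7 of them in the region
  el <- data.frame(start = c(seq(2, 8, length.out = 7),           # in [0, 10)
                             seq(15, 99, length.out = 13)))
  r <- poisson_br_test(c(0, 10), el, chrom_length = 100)
  expect_equal(r$lambda, 2)
  expect_equal(r$observed, 7L)
  hand <- 1 - sum(exp(-2) * 2^(0:6) / factorial(0:6))
  expect_equal(r$p_value, hand, tolerance = 1e-12)
  expect_equal(round(r$p_value, 6), 0.004534)

  # zero observed -> upper tail is 1
  r0 <- poisson_br_test(c(90, 100), data.frame(start = numeric(0)), 100)
  expect_equal(r0$p_value, 1)
  expect_error(poisson_br_test(c(0, 200), el, 100), "shorter than one bin")
  expect_error(poisson_br_test(c(5, 5), el, 100), "length must be > 0")
})

test_that("p-values are non-increasing in the observed count for fixed lambda", {
  base <- data.frame(start = seq(15, 99, length.out = 13))
  prev <- 1
  for (x in 1:8) {
    el <- rbind(base, data.frame(start = seq(1, 9, length.out = x)))
    p <- poisson_br_test(c(0, 10), el, 100)$p_value
    expect_lte(p, prev)
    prev <- p
  }
})

test_that("coding-masked tests reduce to unmasked with an empty mask and drop coding elements", {
  el <- data.frame(start = c(5, 25, 45, 65, 85))
  plain <- poisson_br_test(c(0, 20), el, 100)
  empty_mask <- poisson_br_test(c(0, 20), el, 100,
                                coding_mask = data.frame(start = numeric(0),
                                                         end = numeric(0)))
  expect_equal(empty_mask$lambda, plain$lambda)
  expect_equal(empty_mask$p_value, plain$p_value)
  expect_false(empty_mask$masked_coding)

  # mask covering starts at 25 and 45 drops those elements and their bp
  masked <- poisson_br_test(c(0, 20), el, 100,
                            coding_mask = data.frame(start = c(20, 40),
                                                     end = c(30, 50)))
  expect_true(masked$masked_coding)
  expect_equal(masked$observed, 1L)
  # rate: 3 noncoding elements / 80 noncoding bp, region noncoding width 20
  expect_equal(masked$lambda, 3 / 80 * 20)
})

test_that("neighborhood profiles tile the flanks with BR-width bars", {
  set.seed(3)
  el <- data.frame(start = runif(500, 0, 1e6), group = "dna_transposon")
  prof <- neighborhood_profile(list(start = 5e5, end = 5.1e5, br_id = "II"),
                               el, 1e6, group = "dna_transposon")
  expect_equal(nrow(prof), 11L)               # 5 + BR + 5 for a 10 kb region
  expect_equal(unique(prof$width), 1e4)
  expect_equal(sum(prof$is_br), 1L)
  expect_equal(prof$start[1], 5e5 - 5e4)
  # bar counts sum to the count over the whole span
  expect_equal(sum(prof$count),
               count_in_region(el, c(prof$start[1], prof$end[11])))

  # truncation at the chromosome start
  prof2 <- neighborhood_profile(list(start = 2.5e4, end = 3.5e4), el, 1e6)
  expect_lt(nrow(prof2), 11L)
  expect_equal(prof2$start[1], 0)
  expect_true(all(prof2$width <= 1e4))
  expect_error(neighborhood_profile(list(start = 10, end = 500), el, 1e6),
               "1 kb")
})

test_that("uniform repeats give BR bars near the chromosome mean", {
  cfg <- simulation_config(block_lengths = rep(4e5, 5), block_genes = rep(20, 5),
                           br_lengths = rep(1e4, 4), seed = 31L)
  sim <- simulate_chromosome(cfg)
  br <- sim$truth$br_intervals[2, ]
  prof <- neighborhood_profile(list(start = br$start, end = br$end),
                               sim$repeats, cfg$chrom_length,
                               group = "dna_transposon")
  lam <- attr(prof, "lambda_ref")
  br_count <- prof$count[prof$is_br]
  expect_lt(abs(br_count - lam), 5 * sqrt(lam) + 1)   # within Poisson noise
})

test_that("one-way gene-density ANOVA reproduces a hand-computed F", {
  # two blocks of three 100-kb bins with counts 1,2,3 and 4,5,6 -> F = 13.5
  mk_genes <- function(bin_starts, counts, id0) {
    starts <- unlist(mapply(function(s, k) if (k) s + seq_len(k) * 1000 else numeric(0),
                            bin_starts, counts))
    data.frame(gene_id = paste0("h", id0 + seq_along(starts)), chrom = "X",
               start = starts, end = starts + 500, strand = "+",
               stringsAsFactors = FALSE)
  }
  ann <- rbind(mk_genes(c(0, 1e5, 2e5), c(1, 2, 3), 0),
               mk_genes(c(4e5, 5e5, 6e5), c(4, 5, 6), 100))
  blocks <- data.frame(index = c(1, 2), start = c(0, 4e5), end = c(3e5, 7e5))
  res <- gene_density_anova(blocks, ann)
  expect_equal(res$F, 13.5)
  expect_equal(res$bins$count, c(1, 2, 3, 4, 5, 6))

  # identical bins everywhere -> F = 0
  ann2 <- rbind(mk_genes(c(0, 1e5, 2e5), c(2, 2, 2), 0),
                mk_genes(c(4e5, 5e5, 6e5), c(2, 2, 2), 100))
  expect_equal(gene_density_anova(blocks, ann2)$F, 0)

  # a block shorter than two bins is an error naming the block
  blocks3 <- data.frame(index = c(1, 9), start = c(0, 4e5), end = c(3e5, 4.5e5))
  expect_error(gene_density_anova(blocks3, ann), "block 9")
})
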