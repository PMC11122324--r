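test_that("maximal bi-consecutive runs become blocks with correct ranks and signs", {
  res <- delineate_blocks(paste0("g", 1:6), paste0("g", c(1, 2, 5, 6, 3, 4)))
  expect_equal(nrow(res$blocks), 3L)
  expect_equal(res$blocks$member_genes,
               list(c("g1", "g2"), c("g3", "g4"), c("g5", "g6")))
  expect_equal(res$blocks$sign, c(1L, 1L, 1L))
  expect_equal(res$blocks$target_rank, c(1L, 3L, 2L))
  expect_equal(res$singletons, character(0))

  ident <- delineate_blocks(paste0("g", 1:8), paste0("g", 1:8))
  expect_equal(nrow(ident$blocks), 1L)
  expect_equal(ident$blocks$n_genes, 8L)

  expect_error(delineate_blocks(c("a", "b"), c("a", "c")), "symmetric difference")
})

test_that("an inverted segment yields a negative-sign block and the right permutation", {
  # 4-gene toy: target reverses the middle pair
  res <- delineate_blocks(paste0("g", 1:4), c("g1", "g3", "g2", "g4"))
  # g3,g2 is a descending run; g1 and g4 are singletons
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$sign, -1L)
  expect_setequal(res$singletons, c("g1", "g4"))

  # embed as full permutation over two flanking 2-gene blocks
  res2 <- delineate_blocks(paste0("g", 1:6), c("g1", "g2", "g4", "g3", "g5", "g6"))
  expect_equal(to_signed_permutation(res2$blocks), c(1L, -2L, 3L))
})

test_that("single-gene transpositions are singletons, never blocks", {
  res <- delineate_blocks(paste0("g", 1:5), c("g1", "g2", "g5", "g3", "g4"))
  expect_equal(res$singletons, "g5")
  expect_true(all(res$blocks$n_genes >= 2L))
  # gene conservation
  expect_equal(sum(res$blocks$n_genes) + length(res$singletons), 5L)
})

test_that("swapping reference and target gives the inverse arrangement", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    genes <- paste0("g", seq_len(n))
    tgt <- paste0("g", sample(n))
    fwd <- delineate_blocks(genes, tgt)
    bwd <- delineate_blocks(tgt, genes)
    expect_equal(nrow(fwd$blocks), nrow(bwd$blocks))
    expect_equal(length(fwd$singletons), length(bwd$singletons))
    expect_equal(sum(fwd$blocks$n_genes) + length(fwd$singletons), n)
    if (nrow(fwd$blocks) > 0 && setequal(fwd$blocks$target_rank,
                                         seq_len(nrow(fwd$blocks)))) {
      pf <- to_signed_permutation(fwd$blocks)
      pb <- to_signed_permutation(bwd$blocks)
      # inverse signed permutation
      inv <- integer(length(pf))
      inv[abs(pf)] <- sign(pf) * seq_along(pf)
      expect_equal(pb, inv)
    }
  }
})

test_that("the study-scale fixture yields five blocks arranged 1 -4 3 -2 5", {
  sim <- simulate_chromosome(paper_scale_config(seed = 11L))
  res <- delineate_blocks(sim$genes$gene_id, sim$target$gene_id)
  expect_equal(nrow(res$blocks), 5L)
  expect_equal(res$blocks$n_genes, c(122L, 42L, 722L, 137L, 199L))
  expect_equal(res$singletons, character(0))
  expect_equal(to_signed_permutation(res$blocks), c(1L, -4L, 3L, -2L, 5L))
  # recovered boundaries equal planted boundaries exactly
  met <- block_metrics(res$blocks, sim$genes)
  expect_equal(met$start, sim$truth$block_start)
  expect_equal(met$end, sim$truth$block_end)
})

test_that("breakpoint regions are the inter-block gene gaps, labelled I..N", {
  ann <- toy_annotation(4, len = 1000, gap = 0)
  ann$start <- c(0, 2000, 12000, 20000)
  ann$end <- c(1000, 5000, 15000, 23000)
  blocks <- delineate_blocks(ann$gene_id, c("g1", "g2", "g4", "g3"))$blocks
  # blocks {g1,g2} and {g3,g4}
  brs <- locate_breakpoint_regions(blocks, ann)
  expect_equal(brs$br_id, "I")
  expect_equal(brs$start, 5000)
  expect_equal(brs$end, 12000)
  expect_equal(brs$length, 7000)

  # abutting flank genes -> zero-length region is an error
  ann2 <- ann
  ann2$start <- c(0, 1000, 5000, 8000)
  ann2$end <- c(1000, 5000, 5000 + 3000, 11000)
  ann2$end[2] <- 5000
  expect_error(locate_breakpoint_regions(blocks, ann2), "zero-length")

  sim <- simulate_chromosome(paper_scale_config(seed = 11L))
  res <- delineate_blocks(sim$genes$gene_id, sim$target$gene_id)
  brs <- locate_breakpoint_regions(res$blocks, sim$genes)
  expect_equal(brs$br_id, c("I", "II", "III", "IV"))
  expect_equal(brs$start, sim$truth$br_intervals$start)
  expect_equal(brs$end, sim$truth$br_intervals$end)
})

test_that("block metrics reproduce the gene-density arithmetic", {
  sim <- simulate_chromosome(paper_scale_config(seed = 11L))
  res <- delineate_blocks(sim$genes$gene_id, sim$target$gene_id)
  met <- block_metrics(res$blocks, sim$genes)
  expect_equal(met$length_bp,
               c(1458895, 526550, 10348225, 2148753, 3273690))
  expect_equal(met$density_rounded[1], 8.36)   # 122 genes / 1,458,895 bp
  expect_equal(met$density_rounded[3], 6.98)   # 722 genes / 10,348,225 bp
  expect_equal(sum(met$length_bp), 17756113)
  expect_equal(sum(met$n_genes), 1222L)
})

test_that("capture statistics sum gene and bp content over block subsets", {
  sim <- simulate_chromosome(paper_scale_config(seed = 11L))
  res <- delineate_blocks(sim$genes$gene_id, sim$target$gene_id)
  outer <- capture_stats(c(2L, 3L, 4L), res$blocks, sim$genes)
  expect_equal(outer$n_genes, 901L)
  expect_equal(outer$total_bp, 13023528)
  inner <- capture_stats(3L, res$blocks, sim$genes)
  expect_equal(inner$n_genes, 722L)
  expect_equal(inner$total_bp, 10348225)
  none <- capture_stats(integer(0), res$blocks, sim$genes)
  expect_equal(none$n_genes, 0L)
  expect_equal(none$total_bp, 0)
  expect_error(capture_stats(9L, res$blocks, sim$genes), "unknown block")
})
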