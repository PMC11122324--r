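# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Minimal gene annotation: ids g1..gn, consecutive intervals of `len` bp
# separated by `gap` bp, starting at `offset`.
toy_annotation <- function(n, len = 1000, gap = 500, offset = 0, chrom = "X") {
  start <- offset + (seq_len(n) - 1) * (len + gap)
  data.frame(gene_id = paste0("g", seq_len(n)), chrom = chrom,
             start = start, end = start + len,
             strand = rep("+", n), stringsAsFactors = FALSE)
}

# Write a tiny GFF3 gene file (1-based inclusive coordinates on disk).
write_toy_gff3 <- function(rows, path) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(rows)), function(i) {
               paste(rows$chrom[i], "toy", "gene", rows$start1[i], rows$end1[i],
                     ".", rows$strand[i], ".", paste0("ID=", rows$gene_id[i]),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  path
}

# Small simulation used across tests: 5 blocks, nested two-inversion
# scenario, fast to generate.
small_sim <- function(seed = 1L, ...) {
  simulate_chromosome(simulation_config(
    block_lengths = c(3e5, 1.5e5, 5e5, 2e5, 2.5e5),
    block_genes = c(20L, 10L, 35L, 15L, 18L),
    br_lengths = c(9000, 8000, 12000, 7000),
    seed = seed, ...
  ))
}

# All permutations of 1..n (list of integer vectors).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(combinat_perms(n - 1L), function(rest) {
      v <- seq_len(n)[-i]
      c(i, v[rest])
    })
  }))
}

# All 2^n sign vectors of length n.
sign_patterns <- function(n) {
  grid <- expand.grid(rep(list(c(1L, -1L)), n))
  lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
}

expect_scenario_setequal <- function(scenarios, expected) {
  key <- function(m) paste(apply(m, 1L, paste, collapse = ","), collapse = ";")
  expect_setequal(vapply(scenarios, key, character(1)),
                  vapply(expected, key, character(1)))
}
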