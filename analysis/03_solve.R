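#!/usr/bin/env Rscript
# Stage 3 — reconstruct the minimal inversion scenario.
#
# Solves the block arrangement from stage 2 (falling back to the packaged
# arrangement file if stage 2 has not run) for the exact signed reversal
# distance and all minimal scenarios. For the nested two-inversion
# arrangement 1 -4 3 -2 5 there are exactly two ordered scenarios — the
# inner inversion first or the outer first — and the data cannot order
# them, so both are reported.

suppressMessages(library(invmap))
out <- "results"
dir.create(out, showWarnings = FALSE)

path <- file.path(out, "block_arrangements.txt")
if (!file.exists(path))
  path <- system.file("extdata", "x_block_arrangements.txt", package = "invmap")
perms <- read_signed_permutations(path)
src <- perms[[1L]]; tgt <- perms[[2L]]

d <- reversal_distance(src, tgt)
sc <- enumerate_minimal_scenarios(src, tgt)

jsonlite::write_json(
  list(source = src, target = tgt, distance = d,
       n_scenarios = length(sc), truncated = attr(sc, "truncated"),
       scenarios = lapply(sc, function(m)
         apply(m, 1L, function(r) list(i = r[[1]], j = r[[2]])))),
  file.path(out, "reversal_scenarios.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("distance %d between %s and %s\n", d,
            paste(src, collapse = " "), paste(tgt, collapse = " ")))
cat(sprintf("%d minimal scenario(s):\n", length(sc)))
for (k in seq_along(sc)) {
  steps <- apply(sc[[k]], 1L, function(r) sprintf("reverse[%d..%d]", r[1], r[2]))
  cat(sprintf("  scenario %d: %s\n", k, paste(steps, collapse = " then ")))
}
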