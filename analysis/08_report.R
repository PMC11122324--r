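#!/usr/bin/env Rscript
# Stage 8 — aggregate the stage outputs into one report (JSON + Markdown).

suppressMessages(library(invmap))
out <- "results"

syn <- jsonlite::read_json(file.path(out, "synteny_summary.json"))
rev <- jsonlite::read_json(file.path(out, "reversal_scenarios.json"))
anc <- jsonlite::read_json(file.path(out, "ancestry_report.json"))
anova <- jsonlite::read_json(file.path(out, "gene_density_anova.json"))
blocks <- utils::read.delim(file.path(out, "synteny_blocks.tsv"))
brs <- utils::read.delim(file.path(out, "breakpoint_regions.tsv"))
camp <- utils::read.delim(file.path(out, "campaign_log.tsv"))

report <- list(synteny = syn, reversals = rev, ancestry = anc, anova = anova)
jsonlite::write_json(report, file.path(out, "report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

md <- c(
  "# Inversion mapping report", "",
  "## Synteny blocks", "",
  "| block | length (bp) | genes | density /100kb | target rank | sign |",
  "|---|---|---|---|---|---|",
  sprintf("| %d | %s | %d | %.2f | %d | %+d |",
          blocks$index, format(blocks$length_bp, big.mark = ","),
          blocks$n_genes, blocks$density_per_100kb, blocks$target_rank,
          blocks$sign),
  "",
  sprintf("Total: %s bp, %d genes across %d blocks; %d breakpoint regions (%s).",
          format(syn$total_block_bp, big.mark = ","), syn$total_genes,
          syn$n_blocks, nrow(brs), paste(brs$br_id, collapse = ", ")),
  "",
  "## Reversal scenario", "",
  sprintf("Arrangement `%s` vs `%s`: distance **%d**, %d minimal scenario(s).",
          paste(unlist(rev$source), collapse = " "),
          paste(unlist(rev$target), collapse = " "),
          rev$distance, rev$n_scenarios),
  "",
  "## Iterative mapping", "",
  sprintf("%d rounds, final total interval width %s bp.",
          max(camp$round), format(min(camp$total_width), big.mark = ",")),
  "",
  "## Ancestry", "",
  sprintf("Verdict: **%s** (%d regions support A, %d support B, %d undetermined).",
          anc$verdict, anc$n_a, anc$n_b, anc$n_undetermined),
  "",
  "## Gene density", "",
  sprintf("One-way ANOVA across blocks: F = %.3f, p = %.3f.",
          anova$F, anova$p_value)
)
writeLines(md, file.path(out, "report.md"))
cat("wrote", file.path(out, "report.json"), "and", file.path(out, "report.md"), "\n")
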