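#!/usr/bin/env Rscript
# Stage 2 — delineate synteny blocks and breakpoint regions.
#
# Reads the reference annotation and the target-species gene order written
# by stage 1, finds maximal bi-consecutive gene runs (blocks of >= 2 genes),
# extracts the inter-block breakpoint regions, and tabulates block lengths,
# gene counts and densities plus the gene/bp capture of the two inversions.

suppressMessages(library(invmap))
out <- "results"

ann <- read_gff3(file.path(out, "reference_genes.gff3"))
target <- utils::read.delim(file.path(out, "target_gene_order.tsv"))

res <- delineate_blocks(ann$gene_id, target$gene_id)
met <- block_metrics(res$blocks, ann)
brs <- locate_breakpoint_regions(res$blocks, ann)
perm <- to_signed_permutation(res$blocks)

blocks_out <- cbind(res$blocks[, c("index", "first_gene", "last_gene",
                                   "n_genes", "target_rank", "sign")],
                    met[, c("start", "end", "length_bp",
                            "density_per_100kb", "density_rounded")])
utils::write.table(blocks_out, file.path(out, "synteny_blocks.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(brs, file.path(out, "breakpoint_regions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_signed_permutations(list(reference = seq_along(perm), target = perm),
                          file.path(out, "block_arrangements.txt"))

outer <- capture_stats(c(2L, 3L, 4L), res$blocks, ann)
inner <- capture_stats(3L, res$blocks, ann)
jsonlite::write_json(
  list(n_blocks = nrow(res$blocks), n_breakpoint_regions = nrow(brs),
       n_singletons = length(res$singletons),
       total_block_bp = sum(met$length_bp), total_genes = sum(met$n_genes),
       target_arrangement = perm,
       outer_inversion = outer, inner_inversion = inner),
  file.path(out, "synteny_summary.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("%d blocks (%s genes) over %s bp; %d breakpoint regions\n",
            nrow(res$blocks), sum(met$n_genes),
            format(sum(met$length_bp), big.mark = ","), nrow(brs)))
cat(sprintf("target arrangement: %s\n", paste(perm, collapse = " ")))
cat(sprintf("outer inversion: %d genes (%.1f%%), %.2f Mb; inner: %d genes (%.1f%%), %.2f Mb\n",
            outer$n_genes, 100 * outer$gene_fraction, outer$total_bp / 1e6,
            inner$n_genes, 100 * inner$gene_fraction, inner$total_bp / 1e6))
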