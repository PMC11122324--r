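# Annotation I/O. All coordinates are 0-based half-open internally; GFF3
# (1-based inclusive) is converted at the boundary, BED is native. Interval
# length is therefore always end - start.

#' Default repeat family-to-group mapping
#'
#' Maps repeat family labels (as emitted by RepeatMasker-style summaries)
#' to the four analysis groups: class I retrotransposons (LTR Gypsy/Copia,
#' LINEs), class II DNA transposons (TIR families and Helitrons), unknown
#' TEs, and simple/low-complexity repeats. Patterns are matched
#' case-insensitively as substrings, first hit wins; labels matching no
#' pattern fall back to `unknown_te` with a warning at read time.
#'
#' @return A data frame with columns `pattern` and `group`.
#' @export
default_repeat_groups <- function() {
  data.frame(
    pattern = c("Gypsy", "Copia", "LTR", "LINE",
                "CACTA", "Mutator", "PIF_Harbinger", "Harbinger",
                "Tc1_Mariner", "Mariner", "hAT", "Helitron",
                "DTC", "DTA", "DTH", "DTT", "DTM",
                "Low_complexity", "Simple_repeat", "Satellite",
                "Repeat_region", "Unknown"),
    group = c(rep("retrotransposon", 4L),
              rep("dna_transposon", 13L),
              rep("simple_repeat", 3L),
              rep("unknown_te", 2L)),
    stringsAsFactors = FALSE
  )
}

.repeat_group_of <- function(labels, family_map) {
  out <- rep(NA_character_, length(labels))
  for (r in seq_len(nrow(family_map))) {
    hit <- is.na(out) & grepl(family_map$pattern[r], labels,
                              ignore.case = TRUE, fixed = FALSE)
    out[hit] <- family_map$group[r]
  }
  out
}

#' Read gene annotations from a GFF3 file
#'
#' Reads `gene`-type features, requiring an `ID` attribute, and converts
#' 1-based inclusive GFF coordinates to the internal 0-based half-open
#' convention. Records are sorted by (chrom, start).
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path, warn = FALSE)
  body <- !startsWith(raw, "#") & nzchar(trimws(raw))
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                 bad, nfield[which(nfield != 9L)[1L]]))
  }
  if (!any(body)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("GFF3 gene feature without an ID attribute")
  ann <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,      # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  dup <- ann$gene_id[duplicated(paste(ann$chrom, ann$gene_id))]
  if (length(dup))
    stop(sprintf("duplicate gene ID within a chromosome: %s",
                 paste(unique(dup), collapse = ", ")))
  if (any(ann$start >= ann$end)) stop("gene with start >= end after conversion")
  ann[order(ann$chrom, ann$start), , drop = FALSE]
}

#' Write gene annotations to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open intervals are
#' converted back to 1-based inclusive on output, so read-write-read is the
#' identity.
#'
#' @param annotation Data frame as returned by [read_gff3()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(annotation, path, source = "invmap") {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1, end = annotation$end),
    strand = annotation$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read repeat annotations from a BED4 file
#'
#' BED coordinates are 0-based half-open, matching the internal convention,
#' so no conversion is applied. Column 4 carries the repeat family label,
#' which is mapped to one of the four analysis groups; labels matching no
#' pattern are assigned `unknown_te` with a warning.
#'
#' @param path BED file path (3+ columns, tab- or space-separated).
#' @param family_map Data frame with `pattern`, `group` columns; defaults to
#'   [default_repeat_groups()].
#' @return Data frame with `chrom`, `start`, `end`, `family_label`, `group`.
#' @export
read_repeat_bed <- function(path, family_map = default_repeat_groups()) {
  stopifnot(all(c("pattern", "group") %in% names(family_map)))
  tab <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(tab) < 3L) stop("BED file must have at least 3 columns")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4L] <- "family_label"
  else tab$family_label <- "Unknown"
  tab$family_label[is.na(tab$family_label) | !nzchar(tab$family_label)] <- "Unknown"
  if (any(tab$end <= tab$start)) {
    bad <- which(tab$end <= tab$start)[1L]
    stop(sprintf("invalid repeat interval at row %d: end (%s) <= start (%s)",
                 bad, tab$end[bad], tab$start[bad]))
  }
  grp <- .repeat_group_of(tab$family_label, family_map)
  if (anyNA(grp)) {
    warning(sprintf("%d repeat label(s) matched no family pattern, assigned unknown_te: %s",
                    sum(is.na(grp)),
                    paste(unique(tab$family_label[is.na(grp)]), collapse = ", ")))
    grp[is.na(grp)] <- "unknown_te"
  }
  out <- data.frame(chrom = tab$chrom, start = as.numeric(tab$start),
                    end = as.numeric(tab$end), family_label = tab$family_label,
                    group = grp, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write repeat annotations to BED4
#'
#' @param repeats Data frame as returned by [read_repeat_bed()].
#' @param path Output path.
#' @export
write_repeat_bed <- function(repeats, path) {
  utils::write.table(
    repeats[, c("chrom", "start", "end", "family_label")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a FISH marker-localization table
#'
#' TSV with header and columns `gene_id`, `ref_coord`, `zone`, `round`, and
#' optionally `channel`. Zones are validated against the declared ordered
#' zone list of the target chromosome (centromere-to-telomere or the
#' reverse, fixed by the configuration). Duplicate (gene, round) rows keep
#' the first occurrence with a warning. Rows are stably sorted by
#' (round, ref_coord).
#'
#' @param path TSV path.
#' @param zone_order Character vector of allowed zone labels in
#'   chromosomal order.
#' @return Data frame with the above columns plus `zone_rank` (position of
#'   the zone in `zone_order`).
#' @export
read_marker_table <- function(path, zone_order) {
  stopifnot(is.character(zone_order), length(zone_order) >= 1L)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "ref_coord", "zone", "round")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("marker table missing column(s): %s", paste(miss, collapse = ", ")))
  if (!"channel" %in% names(tab)) tab$channel <- NA_character_
  unknown <- setdiff(unique(tab$zone), zone_order)
  if (length(unknown))
    stop(sprintf("unknown zone label(s): %s; allowed: %s",
                 paste(unknown, collapse = ", "),
                 paste(zone_order, collapse = ", ")))
  if (any(tab$round < 1)) stop("round indices must be >= 1")
  key <- paste(tab$gene_id, tab$round)
  if (anyDuplicated(key)) {
    warning(sprintf("dropping %d duplicate (gene, round) row(s), keeping first",
                    sum(duplicated(key))))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  tab$zone_rank <- match(tab$zone, zone_order)
  tab <- tab[order(tab$round, tab$ref_coord), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("gene_id", "ref_coord", "zone", "zone_rank", "round", "channel")]
}

#' Write a FISH marker-localization table
#'
#' @param markers Data frame with at least `gene_id`, `ref_coord`, `zone`,
#'   `round` (and optionally `channel`).
#' @param path Output path.
#' @export
write_marker_table <- function(markers, path) {
  cols <- intersect(c("gene_id", "ref_coord", "zone", "round", "channel"),
                    names(markers))
  utils::write.table(markers[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Midpoint reference coordinate of genes
#'
#' The single reference-genome point used to order whole-gene FISH probes:
#' the integer midpoint of the gene interval. Strand is deliberately not
#' used for marker ordering (probe orientation on the target chromosome
#' comes from dual-channel gene pairs, not from reference strand).
#'
#' @param annotation Gene annotation data frame.
#' @return Numeric vector of midpoints.
#' @export
gene_midpoint <- function(annotation) {
  floor((annotation$start + annotation$end) / 2)
}
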