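## Gene-model IO (GFF3, gene/exon features only).
##
## A gene model is stored as a flat exon table: one row per exon with
## 0-based half-open coordinates; introns are the gaps between consecutive
## exons of a gene. GFF3 (1-based inclusive) is converted at this boundary.

gene_cols <- c("gene_id", "contig", "strand", "exon_start", "exon_end")

#' Read gene models from GFF3
#'
#' Reads `gene` and `exon` features (the only types this package interprets;
#' `mRNA` is tolerated and resolved to its parent gene). Exons are attached
#' to genes through their `Parent` attribute.
#'
#' @param path GFF3 file.
#' @return A `data.table` with one row per exon: `gene_id`, `contig`,
#'   `strand`, `exon_start`, `exon_end` (0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  ## resolve mRNA -> gene so exons may point at either level
  parent_of <- setNames(
    vapply(g$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    g$ID)
  gene_ids <- g$ID[type == "gene"]
  ex <- g[type == "exon"]
  if (!length(ex)) return(empty_gene_models())
  par <- vapply(ex$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                character(1))
  ## one hop up if the parent is an mRNA
  hop <- par %in% names(parent_of) & !(par %in% gene_ids)
  par[hop] <- parent_of[par[hop]]
  x <- data.table::data.table(
    gene_id = par,
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    exon_start = GenomicRanges::start(ex) - 1L,
    exon_end = GenomicRanges::end(ex))
  validate_gene_models(x, path)
}

empty_gene_models <- function() {
  data.table::data.table(gene_id = character(), contig = character(),
                         strand = character(),
                         exon_start = integer(), exon_end = integer())
}

validate_gene_models <- function(x, path = "<table>") {
  if (!nrow(x)) return(x[])
  data.table::setorder(x, gene_id, exon_start)
  overlap <- x[, any(exon_start[-1] < exon_end[-.N]), by = gene_id]
  bad <- overlap[V1 == TRUE, gene_id]
  if (length(bad))
    stopf("gene model %s: overlapping exons within gene(s) %s",
          path, paste(head(bad, 5), collapse = ", "))
  x[]
}

#' Write gene models to GFF3
#'
#' @param x Exon table as returned by [read_gene_models()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(x, path) {
  x <- validate_gene_models(data.table::as.data.table(x))
  genes <- x[, .(start0 = min(exon_start), end0 = max(exon_end),
                 contig = contig[1], strand = strand[1]), by = gene_id]
  gene_rows <- sprintf("%s\tarmsraceTE\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$contig, genes$start0 + 1L, genes$end0,
                       genes$strand, genes$gene_id)
  exon_rows <- sprintf(
    "%s\tarmsraceTE\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
    x$contig, x$exon_start + 1L, x$exon_end, x$strand,
    x$gene_id, x[, seq_len(.N), by = gene_id]$V1, x$gene_id)
  writeLines(c("##gff-version 3", gene_rows, exon_rows), path)
  invisible(path)
}

#' Intron intervals of a gene-model table
#'
#' @param x Exon table as returned by [read_gene_models()].
#' @return A `data.table` with `gene_id`, `contig`, `strand`, `intron_start`,
#'   `intron_end` (0-based half-open); genes with one exon contribute none.
#' @export
gene_introns <- function(x) {
  x <- data.table::as.data.table(x)
  data.table::setorder(x, gene_id, exon_start)
  x[, if (.N > 1L)
    .(contig = contig[1], strand = strand[1],
      intron_start = exon_end[-.N], intron_end = exon_start[-1]),
    by = gene_id]
}
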