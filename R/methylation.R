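## CpG methylation calling and per-family / per-superfamily aggregation.
##
## Site calling is deliberately strict about boundaries: coverage 10x and
## 50x are both evaluable ("between 10 to 50x" read inclusively), while a
## methylation probability of exactly 0.80 is unmethylated ("over 80%" read
## strictly); the same strictness applies to the >30-CpG family filter.
## All four boundaries are arguments.

#' Call methylation status per CpG site
#'
#' @param records CpG table ([read_cpg_table()]).
#' @param min_coverage,max_coverage Evaluable coverage window, inclusive
#'   (defaults 10 and 50).
#' @param prob_threshold Methylated iff `meth_prob` strictly exceeds this
#'   (default 0.80).
#' @return The input table plus a `status` column:
#'   `methylated` / `unmethylated` / `excluded`.
#' @export
call_sites <- function(records, min_coverage = 10L, max_coverage = 50L,
                       prob_threshold = 0.80) {
  x <- data.table::copy(data.table::as.data.table(records))
  x[, status := data.table::fifelse(
    coverage < min_coverage | coverage > max_coverage, "excluded",
    data.table::fifelse(meth_prob > prob_threshold,
                        "methylated", "unmethylated"))]
  x[]
}

#' Genome-wide background methylation level
#'
#' Fraction of evaluable CpG sites called methylated over the whole genome.
#'
#' @param calls Output of [call_sites()].
#' @return Fraction in `[0, 1]`.
#' @export
genome_background <- function(calls) {
  calls <- data.table::as.data.table(calls)
  n_meth <- calls[status == "methylated", .N]
  n_eval <- calls[status != "excluded", .N]
  if (n_eval == 0L) stopf("no evaluable CpG sites (all excluded)")
  n_meth / n_eval
}

#' Per-family pooled CpG methylation
#'
#' Pools evaluable CpG sites over all copies of each family. A site under
#' two copies of one family counts once; a site under copies of two
#' different families counts once in each (families pool independently).
#' Families with 30 or fewer evaluable sites fail QC and should be dropped
#' from downstream statistics; their percentage is still reported when at
#' least one site exists, but `normalized_level` only when QC passes.
#'
#' @param calls Output of [call_sites()].
#' @param copies Linked-copy table ([link_fragments()]) restricted to one
#'   genome; intervals 0-based half-open.
#' @param background Genome background fraction (> 0), from
#'   [genome_background()].
#' @param min_sites QC floor: pass iff evaluable sites strictly exceed this
#'   (default 30).
#' @return A `data.table` per family: `n_sites`, `n_methylated`,
#'   `pct_methylated` (fraction), `normalized_level`
#'   (`pct_methylated / background`), `qc_pass`.
#' @export
family_methylation <- function(calls, copies, background, min_sites = 30L) {
  assert_number(background, "background", lower = 0)
  if (background == 0) stopf("background methylation level of 0 is degenerate")
  calls <- data.table::as.data.table(calls)[status != "excluded"]
  copies <- data.table::as.data.table(copies)
  fams <- unique(copies$family_id)
  if (!nrow(calls) || !nrow(copies)) {
    out <- data.table::data.table(
      family_id = fams, n_sites = 0L, n_methylated = 0L,
      pct_methylated = NA_real_, normalized_level = NA_real_,
      qc_pass = FALSE)
    return(out)
  }
  site_gr <- GenomicRanges::GRanges(
    calls$contig, IRanges::IRanges(start = calls$pos + 1L, width = 1L))
  copy_gr <- GenomicRanges::GRanges(
    copies$contig, IRanges::IRanges(start = copies$start + 1L,
                                    end = copies$end))
  ## disjoint contig sets are a legitimate "no overlap", not a problem
  ov <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, copy_gr))
  hits <- data.table::data.table(
    site = S4Vectors::queryHits(ov),
    family_id = copies$family_id[S4Vectors::subjectHits(ov)])
  hits <- unique(hits)                       # one count per (site, family)
  hits[, methylated := calls$status[site] == "methylated"]
  agg <- hits[, .(n_sites = .N, n_methylated = sum(methylated)),
              by = family_id]
  out <- merge(data.table::data.table(family_id = fams), agg,
               by = "family_id", all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, n_methylated = 0L)]
  out[, qc_pass := n_sites > min_sites]
  out[, pct_methylated := ifelse(n_sites > 0, n_methylated / n_sites,
                                 NA_real_)]
  out[, normalized_level := ifelse(qc_pass, pct_methylated / background,
                                   NA_real_)]
  out[]
}

#' Superfamily methylation as the median over member families
#'
#' Only QC-passing families contribute; superfamilies with no passing member
#' are reported missing (`NA`), the "grey in the heatmap" case.
#'
#' @param family_meth Output of [family_methylation()].
#' @param classification `data.table` with `family_id`,
#'   `class_superfamily`.
#' @return A `data.table` per superfamily: `n_families`, `pct_methylated`
#'   (median fraction), `normalized_level` (median).
#' @export
superfamily_methylation <- function(family_meth, classification) {
  x <- merge(data.table::as.data.table(family_meth),
             data.table::as.data.table(classification)[
               , .(family_id, class_superfamily)],
             by = "family_id")
  x[, .(n_families = sum(qc_pass),
        pct_methylated = if (any(qc_pass))
          median(pct_methylated[qc_pass]) else NA_real_,
        normalized_level = if (any(qc_pass))
          median(normalized_level[qc_pass]) else NA_real_),
    by = class_superfamily]
}
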