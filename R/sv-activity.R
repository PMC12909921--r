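## TE-associated structural-variant activity metrics.
##
## Representative selection collapses co-located multi-sample calls; TE
## association is a best-hit local alignment of the SV sequence against the
## family catalog with a coverage floor; region assignment evaluates the
## breakpoint with exon > intron > intergenic precedence.

#' Collapse co-located SV calls to one representative per locus
#'
#' Calls on the same contig with the same `sv_type` whose breakpoints chain
#' within `merge_window` bp form one locus; the call with the longest
#' sequence represents it (ties break to the smallest `sv_id`), and carrier
#' sets are unioned.
#'
#' @param svs SV table ([read_sv_records()]).
#' @param merge_window Breakpoint chaining window in bp (default 100).
#' @return SV table with one row per locus, plus `n_merged`.
#' @export
pick_representative_sv <- function(svs, merge_window = 100L) {
  svs <- data.table::copy(data.table::as.data.table(svs))
  if (!nrow(svs)) stopf("empty SV group")
  data.table::setorder(svs, contig, sv_type, position, sv_id)
  svs[, locus := cumsum(c(1L, (diff(position) > merge_window))),
      by = .(contig, sv_type)]
  out <- svs[, {
    o <- order(-length, sv_id)
    carriers_all <- sort(unique(unlist(
      strsplit(carriers, ",", fixed = TRUE))))
    r <- .SD[o[1]]
    r$carriers <- paste(carriers_all, collapse = ",")
    cbind(r, n_merged = .N)
  }, by = .(contig, sv_type, locus)]
  out[, locus := NULL]
  data.table::setcolorder(out, c(sv_cols, "n_merged"))
  data.table::setorder(out, contig, position)
  out[]
}

#' Annotate an SV sequence with its best-hit TE family
#'
#' Seed-and-extend local alignment (match 2, mismatch -3; see
#' [seed_local_align()], with a full Smith-Waterman fallback when the seed
#' diagonal explains the pair poorly) of the SV sequence against every
#' catalog consensus passing an 11-mer prefilter. The best score wins; the
#' SV is TE-associated only if the aligned bases cover at least `min_cov`
#' of the shorter of SV and consensus. Score ties break to the higher
#' identity, then the smaller `family_id`.
#'
#' @param sv_sequence Nucleotide string (empty: returns no hit, with a
#'   warning).
#' @param catalog Catalog table ([read_consensus_fasta()]).
#' @param min_cov Aligned-fraction floor (default 0.5).
#' @param min_shared_kmers 11-mer prefilter (default 3).
#' @param catalog_index Optional precomputed [kmer_index()] of the catalog
#'   sequences (saves recomputation over many SVs).
#' @return A list with `family_id` (or `NA`), `score`, `identity`,
#'   `coverage`.
#' @export
annotate_sv_te <- function(sv_sequence, catalog, min_cov = 0.5,
                           min_shared_kmers = 3L, catalog_index = NULL) {
  if (!nrow(catalog)) stopf("empty catalog")
  no_hit <- list(family_id = NA_character_, score = NA_real_,
                 identity = NA_real_, coverage = NA_real_)
  if (is.na(sv_sequence) || !nzchar(sv_sequence)) {
    warnf("empty SV sequence; no TE annotation")
    return(no_hit)
  }
  if (is.null(catalog_index)) catalog_index <- kmer_index(catalog$sequence)
  sv_idx <- kmer_index(sv_sequence)
  cand <- shared_kmer_pairs(sv_idx, catalog_index, min_shared_kmers)$s
  if (!length(cand)) return(no_hit)
  best <- no_hit
  for (i in cand[order(catalog$family_id[cand])]) {
    aln <- seed_local_align(sv_sequence, catalog$sequence[i])
    if (is.null(aln) || aln$identity < 0.7)
      aln <- sw_local_align(sv_sequence, catalog$sequence[i])
    cov <- aln$aligned / min(nchar(sv_sequence), catalog$length[i])
    if (cov < min_cov) next
    if (is.na(best$score) || aln$score > best$score ||
        (aln$score == best$score && aln$identity > best$identity))
      best <- list(family_id = catalog$family_id[i], score = aln$score,
                   identity = aln$identity, coverage = cov)
  }
  best
}

#' Annotate a table of SVs against the catalog
#'
#' Batch form of [annotate_sv_te()]: one global k-mer join finds all
#' candidate (SV, family) pairs and their dominant seed diagonals; each
#' candidate is then scored by ungapped extension, with the Smith-Waterman
#' fallback when the diagonal explains the pair poorly. Same scoring,
#' coverage floor, and tie-breaking as the single-SV operation.
#'
#' @param svs Representative SV table ([pick_representative_sv()]).
#' @param catalog Catalog table.
#' @inheritParams annotate_sv_te
#' @return The SV table plus `te_family`, `te_superfamily`, `identity`,
#'   `carrier_count`.
#' @export
annotate_svs <- function(svs, catalog, min_cov = 0.5,
                         min_shared_kmers = 3L) {
  svs <- data.table::copy(data.table::as.data.table(svs))
  cls <- setNames(catalog$class_superfamily, catalog$family_id)
  svs[, te_family := NA_character_]
  svs[, identity := NA_real_]
  nonempty <- which(nzchar(svs$sequence))
  if (length(nonempty) && nrow(catalog)) {
    qidx <- kmer_index(svs$sequence[nonempty])
    cidx <- kmer_index(catalog$sequence)
    j <- merge(qidx[, .(kmer, q = seq_i, qpos = pos)],
               cidx[, .(kmer, s = seq_i, spos = pos)],
               by = "kmer", allow.cartesian = TRUE)
    if (nrow(j)) {
      j[, diag := spos - qpos]
      cnt <- j[, .N, by = .(q, s)][N >= min_shared_kmers]
      dd <- j[, .N, by = .(q, s, diag)]
      data.table::setorder(dd, q, s, -N, diag)
      dd <- dd[!duplicated(dd[, .(q, s)])]
      cand <- merge(cnt[, .(q, s)], dd[, .(q, s, diag)], by = c("q", "s"))
      if (nrow(cand)) {
        res <- lapply(seq_len(nrow(cand)), function(r) {
          qseq <- svs$sequence[nonempty[cand$q[r]]]
          sseq <- catalog$sequence[cand$s[r]]
          aln <- extend_diagonal(qseq, sseq, cand$diag[r])
          if (is.null(aln) || aln$identity < 0.7)
            aln <- sw_local_align(qseq, sseq)
          cov <- aln$aligned / min(nchar(qseq), nchar(sseq))
          list(score = aln$score, identity = aln$identity, coverage = cov)
        })
        cand[, score := vapply(res, `[[`, numeric(1), "score")]
        cand[, identity := vapply(res, `[[`, numeric(1), "identity")]
        cand[, coverage := vapply(res, `[[`, numeric(1), "coverage")]
        cand <- cand[coverage >= min_cov]
        cand[, family_id := catalog$family_id[s]]
        data.table::setorder(cand, q, -score, -identity, family_id)
        best <- cand[!duplicated(q)]
        svs[nonempty[best$q], te_family := best$family_id]
        svs[nonempty[best$q], identity := best$identity]
      }
    }
  }
  svs[, te_superfamily := ifelse(is.na(te_family), NA_character_,
                                 cls[te_family])]
  svs[, carrier_count := sv_carrier_count(carriers)]
  svs[]
}

#' Assign a genomic region to a breakpoint
#'
#' Precedence exon > intron > intergenic, evaluated at the single breakpoint
#' position (an insertion occupies a point in the reference).
#'
#' @param positions Integer vector of 0-based breakpoints.
#' @param contigs Character vector of contigs (recycled if length 1).
#' @param genes Exon table ([read_gene_models()]).
#' @return Character vector: `"exon"`, `"intron"` or `"intergenic"`.
#' @export
assign_region <- function(positions, contigs, genes) {
  genes <- data.table::as.data.table(genes)
  if (length(contigs) == 1L) contigs <- rep(contigs, length(positions))
  pt <- GenomicRanges::GRanges(
    contigs, IRanges::IRanges(start = positions + 1L, width = 1L))
  region <- rep("intergenic", length(positions))
  if (nrow(genes)) {
    introns <- gene_introns(genes)
    if (nrow(introns)) {
      igr <- GenomicRanges::GRanges(
        introns$contig, IRanges::IRanges(start = introns$intron_start + 1L,
                                         end = introns$intron_end))
      region[unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(pt, igr)))] <- "intron"
    }
    egr <- GenomicRanges::GRanges(
      genes$contig, IRanges::IRanges(start = genes$exon_start + 1L,
                                     end = genes$exon_end))
    region[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(pt, egr)))] <- "exon"
  }
  region
}

#' Per-family TE activity metrics
#'
#' `spreading_efficiency` is the TE-associated SV count over the family's
#' reference copy number; families absent from the abundance table (zero
#' or filtered copy number) are excluded from efficiency with a message,
#' never a crash. A family is `highly_active` when its SV count strictly
#' exceeds 3.
#'
#' @param annotated Output of [annotate_svs()] with a `region` column (see
#'   [assign_region()]).
#' @param abundance Filtered abundance table for the reference genome
#'   ([filter_low_copy()]).
#' @param active_cut Highly-active floor: `sv_count > active_cut`
#'   (default 3).
#' @return A `data.table` per family: `sv_count`, `copy_number`,
#'   `spreading_efficiency`, `exonic_insertions`, `total_insertions`,
#'   `exonic_ratio`, `highly_active`.
#' @export
family_activity <- function(annotated, abundance, active_cut = 3L) {
  annotated <- data.table::as.data.table(annotated)
  ab <- data.table::as.data.table(abundance)[, .(family_id, copy_number)]
  x <- annotated[!is.na(te_family)]
  agg <- x[, .(sv_count = .N,
               exonic_insertions = sum(region == "exon" & sv_type == "INS"),
               total_insertions = sum(sv_type == "INS")),
           by = .(family_id = te_family)]
  out <- merge(agg, ab, by = "family_id", all.x = TRUE)
  n_missing <- out[is.na(copy_number), .N]
  if (n_missing)
    message(sprintf(
      "%d families with SVs but no (filtered) reference abundance; excluded from spreading efficiency",
      n_missing))
  out[, spreading_efficiency := ifelse(
    !is.na(copy_number) & copy_number > 0, sv_count / copy_number, NA_real_)]
  out[, exonic_ratio := ifelse(total_insertions > 0,
                               exonic_insertions / total_insertions,
                               NA_real_)]
  out[, highly_active := sv_count > active_cut]
  data.table::setorder(out, family_id)
  out[]
}

#' Length-normalised per-region insertion rates
#'
#' Rates are SV counts divided by total region length; exon vs intron is
#' compared with a two-proportion test (trials = bp). With a zero count the
#' raw ratio is infinite and a Haldane-corrected (+0.5 per cell) ratio is
#' reported alongside.
#'
#' @param regions Character vector of region calls, one per SV.
#' @param genes Exon table ([read_gene_models()]).
#' @param genome_length Total genome length in bp.
#' @return A list: `rates` (`data.table` region/count/bp/rate),
#'   `intron_exon_ratio`, `intron_exon_ratio_haldane`, `chisq`, `p`,
#'   `rate_difference`.
#' @export
lengthnorm_region_rates <- function(regions, genes, genome_length) {
  genes <- data.table::as.data.table(genes)
  exon_bp <- genes[, sum(as.numeric(exon_end - exon_start))]
  introns <- gene_introns(genes)
  intron_bp <- if (nrow(introns))
    introns[, sum(as.numeric(intron_end - intron_start))] else 0
  inter_bp <- genome_length - exon_bp - intron_bp
  if (exon_bp <= 0 || intron_bp <= 0)
    stopf("zero exonic or intronic length; rates undefined")
  counts <- c(exon = sum(regions == "exon"),
              intron = sum(regions == "intron"),
              intergenic = sum(regions == "intergenic"))
  bp <- c(exon = exon_bp, intron = intron_bp, intergenic = inter_bp)
  rates <- data.table::data.table(
    region = names(counts), count = as.integer(counts), bp = bp,
    rate = counts / bp)
  ratio <- (counts["intron"] / intron_bp) / (counts["exon"] / exon_bp)
  ratio_h <- ((counts["intron"] + 0.5) / intron_bp) /
    ((counts["exon"] + 0.5) / exon_bp)
  pt <- suppressWarnings(prop.test(
    x = counts[c("intron", "exon")], n = c(intron_bp, exon_bp),
    correct = FALSE))
  list(rates = rates,
       intron_exon_ratio = unname(ratio),
       intron_exon_ratio_haldane = unname(ratio_h),
       chisq = unname(pt$statistic), p = pt$p.value,
       rate_difference = unname(diff(rev(pt$estimate))))
}
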