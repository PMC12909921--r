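## End-to-end pipeline over a cohort directory written by [write_cohort()]
## (or assembled from real per-species files with the same layout).

#' Run the full TE / methylation arms-race pipeline on a cohort directory
#'
#' Reads the per-species files, builds the non-redundant catalog, links
#' fragments into copies, filters low-copy families, calls presence from
#' effective copy numbers and assigns age groups, computes per-copy KD and
#' family KD profiles (focal species), quantifies family and superfamily
#' methylation against the genome background, annotates population SVs
#' against the catalog and derives activity metrics, and assembles the
#' family-level analysis table.
#'
#' @param dir Cohort directory ([write_cohort()] layout).
#' @param ecn_threshold Presence threshold on ECN (default 5, strict >).
#' @param min_copies Copy-number floor ([filter_low_copy()], default 4).
#' @param min_meth_sites Family methylation QC floor (default 30,
#'   strict >).
#' @param sv_min_cov TE-association coverage floor (default 0.5).
#' @param w_cpg CpG transition weight for KD (default 0.1).
#' @return A list of stage outputs: `catalog`, `clusters`, `copies`,
#'   `abundance`, `abundance_filtered`, `presence`, `ages`, `age_summary`,
#'   `kd`, `kd_profiles`, `background`, `family_meth`, `superfamily_meth`,
#'   `svs_annotated`, `activity`, `families` (the merged analysis table),
#'   `stree`, `genes`, `genome_length`.
#' @export
run_pipeline <- function(dir, ecn_threshold = 5, min_copies = 4L,
                         min_meth_sites = 30L, sv_min_cov = 0.5,
                         w_cpg = 0.1) {
  stree <- read_species_tree(file.path(dir, "tree.nwk"),
                             file.path(dir, "clades.yaml"))
  focal <- stree$focal
  species <- setdiff(stree$chain[[length(stree$chain)]]$species,
                     stree$excluded)
  ## catalog ----------------------------------------------------------------
  libs <- data.table::rbindlist(lapply(species, function(sp)
    read_consensus_fasta(file.path(dir, paste0(sp, "_consensi.fa")), sp)))
  ## redundant multi-species library: same id may appear per species
  libs[, lib_id := paste0(family_id, "@", source_species)]
  redundant <- libs[, .(family_id = lib_id, sequence, length,
                        class_superfamily, source_species)]
  built <- build_catalog(redundant)
  catalog <- built$catalog
  catalog[, family_id := sub("@.*$", "", family_id)]
  catalog <- catalog[!duplicated(family_id)]
  ## copies + abundance -----------------------------------------------------
  copies <- data.table::rbindlist(lapply(species, function(sp) {
    h <- read_repeat_hits(file.path(dir, paste0(sp, ".out")),
                          dialect = "rm_out")
    link_fragments(h, species = sp)
  }))
  abundance <- abundance_table(copies)
  abundance_filtered <- filter_low_copy(abundance, min_copies = min_copies)
  ## age --------------------------------------------------------------------
  presence <- presence_matrix(abundance, catalog[, .(family_id, length)],
                              stree, ecn_threshold = ecn_threshold)
  ages <- assign_ages(presence, stree)
  asum <- age_summary(ages, stree)
  ## divergence (focal) -----------------------------------------------------
  aln_path <- file.path(dir, paste0(focal, "_alignments.tsv"))
  kd <- NULL; kdp <- NULL
  if (file.exists(aln_path)) {
    aln <- data.table::fread(aln_path)
    kd <- copy_kd(aln, w_cpg = w_cpg)
    kdp <- kd_profiles(kd)
  }
  ## methylation (focal) ----------------------------------------------------
  calls <- call_sites(read_cpg_table(file.path(dir,
                                               paste0(focal, "_cpg.tsv"))))
  background <- genome_background(calls)
  fam_meth <- family_methylation(calls, copies[species == focal],
                                 background, min_sites = min_meth_sites)
  sf_meth <- superfamily_methylation(fam_meth,
                                     catalog[, .(family_id,
                                                 class_superfamily)])
  ## SV activity (focal) ----------------------------------------------------
  genes <- read_gene_models(file.path(dir, paste0(focal, "_genes.gff3")))
  svs <- read_sv_records(file.path(dir, paste0(focal, "_svs.vcf")),
                         dialect = "vcf")
  reps <- pick_representative_sv(svs)
  annotated <- annotate_svs(reps, catalog, min_cov = sv_min_cov)
  annotated[, region := assign_region(position, contig, genes)]
  activity <- family_activity(annotated,
                              abundance_filtered[species == focal])
  ## merged family table ----------------------------------------------------
  families <- Reduce(function(a, b) merge(a, b, by = "family_id",
                                          all.x = TRUE),
                     list(abundance_filtered[species == focal,
                                             .(family_id, copy_number,
                                               total_copy_bp)],
                          ages,
                          fam_meth[, .(family_id, n_sites, pct_methylated,
                                       normalized_level, qc_pass)],
                          activity[, .(family_id, sv_count,
                                       spreading_efficiency, exonic_ratio,
                                       highly_active)]))
  families[is.na(sv_count), sv_count := 0L]
  families[, spreading_efficiency := ifelse(
    is.na(spreading_efficiency) & copy_number > 0,
    sv_count / copy_number, spreading_efficiency)]
  gl_len <- genes[, sum(as.numeric(exon_end - exon_start))] # not genome size
  list(catalog = catalog, clusters = built$clusters, copies = copies,
       abundance = abundance, abundance_filtered = abundance_filtered,
       presence = presence, ages = ages, age_summary = asum,
       kd = kd, kd_profiles = kdp,
       background = background, family_meth = fam_meth,
       superfamily_meth = sf_meth,
       svs_annotated = annotated, activity = activity,
       families = families, stree = stree, genes = genes,
       exon_bp = gl_len)
}
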