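## Synthetic TE-evolution cohort with full ground truth.
##
## Families are born on the branches of the path from the focal species to
## the in-group root (plus the sister species' terminal branch), at a rate
## per My of branch. Each family carries: a random consensus, a superfamily
## label, and a methylation fraction drawn from a Beta whose mean (and
## spread) depend on family age — young invaders are heavily methylated,
## ancient families relax back toward background. Copies accumulate in every
## descendant species as an insertion burst at birth plus an exponentially
## decaying trickle; copies erode (expected length halves every
## erosion_halflife My) and diverge from the consensus at 2 * mutation_rate
## * insertion_age. Population SVs are emitted for the focal species at a
## rate that decays with family age and is suppressed by
## exp(-beta * methylation / background); candidate insertion points landing
## in exons are accepted with probability exon_penalty.

#' Build a simulation configuration
#'
#' Defaults define the package's reference study conditions: a nominal 200
#' TE families over the 6-species termite in-group, methylation suppression
#' strong enough that young, heavily methylated families are visibly held
#' back, and erosion/divergence rates placing ancient copies near KD 20-25.
#'
#' @param tree A `species_tree` ([termite_species_tree()] by default).
#' @param family_birth_rate Families per My of birth-eligible branch
#'   (default 200/180: a nominal 200 families).
#' @param init_consensus_length Median consensus length, bp (lognormal
#'   spread 0.1, clamped to 400-2500).
#' @param erosion_halflife My for the expected copy length to halve.
#' @param mutation_rate Substitutions per site per My; per-copy divergence
#'   is `2 * mutation_rate * insertion_age` in expectation.
#' @param meth_young_mean,meth_ancient_mean Mean methylated-CpG fraction of
#'   families of age 0 / of the oldest birth age (linear in between).
#' @param meth_concentration_young,meth_concentration_ancient Beta
#'   concentration at the two age extremes (young families are the more
#'   heterogeneous).
#' @param meth_background Genome background methylation fraction.
#' @param suppression_beta SV-activity multiplier
#'   `exp(-beta * meth / background)`.
#' @param base_activity Expected SVs per (unsuppressed, age-0) family in the
#'   sampled population.
#' @param activity_halflife My for intrinsic mobilisation to halve; also
#'   sets the timescale of the post-birth insertion trickle.
#' @param activity_sd_log Lognormal sd of unexplained per-family activity.
#' @param copy_burst Expected copies inserted in the birth burst, per
#'   species.
#' @param copy_saturation Additional expected copies as the trickle
#'   saturates.
#' @param exon_penalty Acceptance probability of an exonic insertion
#'   relative to a non-exonic one, in (0, 1].
#' @param genome_layout List: `n_contigs`, `genes_per_contig`,
#'   `exons_per_gene`, `exon_length`, `intron_length`, `intergenic_length`
#'   (bp).
#' @param n_population_samples Samples in the focal-species SV panel.
#' @param cpg_rate CpG sites emitted per copy bp.
#' @param background_cpg Background CpG sites per species (outside copies).
#' @param consensus_lineage_divergence Per-lineage divergence of non-focal
#'   consensus library entries (exercises the 90% catalog clustering).
#' @param fragment_mean Mean fragments per copy (geometric, capped at 3).
#' @param seed Integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(tree = termite_species_tree(),
                          family_birth_rate = 200 / 180,
                          init_consensus_length = 1200L,
                          erosion_halflife = 100,
                          mutation_rate = 8e-4,
                          meth_young_mean = 0.33,
                          meth_ancient_mean = 0.077,
                          meth_concentration_young = 2.5,
                          meth_concentration_ancient = 20,
                          meth_background = 0.08,
                          suppression_beta = 0.6,
                          base_activity = 60,
                          activity_halflife = 50,
                          activity_sd_log = 0.6,
                          copy_burst = 22,
                          copy_saturation = 10,
                          exon_penalty = 0.36,
                          genome_layout = list(
                            n_contigs = 8L, genes_per_contig = 80L,
                            exons_per_gene = 8L, exon_length = 400L,
                            intron_length = 1200L,
                            intergenic_length = 80000L),
                          n_population_samples = 6L,
                          cpg_rate = 0.02,
                          background_cpg = 150000L,
                          consensus_lineage_divergence = 0.02,
                          fragment_mean = 1.5,
                          seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("family_birth_rate", "erosion_halflife", "mutation_rate",
               "meth_background", "suppression_beta", "base_activity",
               "activity_halflife", "copy_burst", "copy_saturation",
               "cpg_rate"))
    assert_number(cfg[[nm]], nm, lower = 0)
  assert_number(cfg$exon_penalty, "exon_penalty", lower = 1e-9, upper = 1)
  for (nm in c("meth_young_mean", "meth_ancient_mean", "meth_background"))
    assert_number(cfg[[nm]], nm, lower = 0, upper = 1)
  if (!length(tree$tree$tip.label)) stopf("tree has no tips")
  structure(cfg, class = "cohort_config")
}

## ---- internal geometry ----------------------------------------------------

layout_unit <- function(gl) {
  body <- gl$exons_per_gene * gl$exon_length +
    (gl$exons_per_gene - 1L) * gl$intron_length
  list(body = body,
       unit = body + gl$intergenic_length,
       gene_off = gl$intergenic_length %/% 2L)
}

layout_lengths <- function(gl) {
  u <- layout_unit(gl)
  contig_len <- gl$genes_per_contig * u$unit
  list(contig_len = contig_len, total = contig_len * gl$n_contigs,
       unit = u$unit, body = u$body, gene_off = u$gene_off)
}

## region of a global 0-based position, by layout arithmetic
layout_region <- function(global_pos, gl) {
  L <- layout_lengths(gl)
  off <- global_pos %% L$unit
  off2 <- off - L$gene_off
  pitch <- gl$exon_length + gl$intron_length
  in_body <- off2 >= 0 & off2 < L$body
  in_exon <- in_body & (off2 %% pitch) < gl$exon_length &
    (off2 %/% pitch) < gl$exons_per_gene
  data.table::fifelse(in_exon, "exon",
                      data.table::fifelse(in_body, "intron", "intergenic"))
}

global_to_contig <- function(global_pos, gl) {
  L <- layout_lengths(gl)
  list(contig = sprintf("ctg%d", global_pos %/% L$contig_len + 1L),
       pos = global_pos %% L$contig_len)
}

## gene models shared by every species (one layout, species-tagged ids)
layout_genes <- function(gl, species) {
  L <- layout_lengths(gl)
  pitch <- gl$exon_length + gl$intron_length
  g <- data.table::CJ(contig_i = seq_len(gl$n_contigs),
                      gene_i = seq_len(gl$genes_per_contig),
                      exon_i = seq_len(gl$exons_per_gene))
  g[, gene_id := sprintf("%s_g%04d", species,
                         (contig_i - 1L) * gl$genes_per_contig + gene_i)]
  g[, exon_start := (gene_i - 1L) * L$unit + L$gene_off +
      (exon_i - 1L) * pitch]
  g[, `:=`(contig = sprintf("ctg%d", contig_i),
           strand = "+",
           exon_end = exon_start + gl$exon_length)]
  g[, .(gene_id, contig, strand, exon_start, exon_end)]
}

## ---- sequence helpers -----------------------------------------------------

## K2P-like mutation with a transition:transversion ratio of 2
mutate_sequence <- function(seq, divergence) {
  n <- nchar(seq)
  n_mut <- rbinom(1L, n, min(divergence, 0.7))
  if (n_mut == 0L) return(seq)
  pos <- sample.int(n, n_mut)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  is_ts <- runif(n_mut) < 2 / 3
  ch[pos] <- ifelse(is_ts, transition[ch[pos]],
                    vapply(ch[pos], function(b)
                      sample(transversions[[b]], 1L), character(1)))
  paste(ch, collapse = "")
}

## ---- the simulator --------------------------------------------------------

#' Simulate a multi-species TE cohort with ground truth
#'
#' See the package vignette for the generative model. Deterministic given
#' the config (which includes the seed): the same config yields
#' byte-identical files from [write_cohort()].
#'
#' @param config A [cohort_config()].
#' @return A `te_cohort` list: `config`, `stree`, `families` (truth),
#'   `copies` (per-species placed copies), `hits` (fragmented rm_out-style
#'   annotation), `alignments` (focal copies vs consensus), `cpg`
#'   (per-species CpG tables), `genes`, `svs` (focal population SVs with
#'   truth columns), `copy_counts` (true per family x species counts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  stree <- config$tree
  fams <- draw_families(config, stree)
  copies <- draw_copies(config, fams)
  placed <- place_copies(copies, config)
  focal <- stree$focal
  placed <- realize_sequences(placed, fams, config, focal)
  hits <- fragment_copies(placed, config)
  aln <- placed[species == focal,
                .(family_id, copy_id, consensus_aln, copy_aln)]
  cpg <- draw_cpg(placed, fams, config)
  species_all <- sort(unique(placed$species))
  genes <- data.table::rbindlist(
    lapply(species_all, function(sp)
      cbind(species = sp, layout_genes(config$genome_layout, sp))))
  svs <- draw_svs(fams, config, focal)
  counts <- placed[, .(true_copy_number = .N), by = .(species, family_id)]
  structure(list(config = config, stree = stree, families = fams,
                 copies = placed[, .(species, family_id, copy_id, age,
                                     length, cons_start, strand, contig,
                                     start, end, divergence)],
                 hits = hits, alignments = aln, cpg = cpg, genes = genes,
                 svs = svs, copy_counts = counts),
            class = "te_cohort")
}

## Birth-eligible branches: the edges on the focal-to-root path whose child
## clade contains only non-excluded species, plus the sister species'
## terminal branch.
birth_edges <- function(stree) {
  tr <- stree$tree
  rings <- chain_rings(stree)
  ingroup <- unlist(rings)
  ages <- ape::branching.times(tr)
  tipno <- function(lab) which(tr$tip.label == lab)
  node_age <- function(node)
    if (node <= length(tr$tip.label)) 0 else unname(ages[as.character(node)])
  node_tips <- function(node)
    if (node <= length(tr$tip.label)) tr$tip.label[node]
    else ape::extract.clade(tr, node)$tip.label
  path <- ape::nodepath(tr, from = tipno(stree$focal),
                        to = length(tr$tip.label) + 1L)
  ## consecutive (child, parent) pairs climbing to the root
  edges <- list()
  for (i in seq_len(length(path) - 1L)) {
    child <- path[i]; parent <- path[i + 1L]
    tips <- node_tips(child)
    if (!all(tips %in% ingroup)) break
    edges[[length(edges) + 1L]] <- list(
      label = if (i == 1L) stree$focal else sprintf("stem%d", i - 1L),
      t_min = node_age(child), t_max = node_age(parent),
      species = intersect(tips, ingroup))
  }
  sister <- rings[[2]]
  if (length(sister) == 1L) {
    sp <- sister
    parent_age <- node_age(path[2L])
    edges[[length(edges) + 1L]] <- list(
      label = sp, t_min = 0, t_max = parent_age, species = sp)
  }
  edges
}

superfamily_pool <- c(
  "LINE/BovB", "LINE/Jockey", "LINE/R1", "LTR/Gypsy", "LTR/Copia",
  "DNA/TcMar-Tc1", "DNA/TcMar-Mariner", "DNA/hAT-Ac", "DNA/CMC-EnSpm",
  "RC/Helitron", "SINE/tRNA", "Unclassified")

draw_families <- function(config, stree) {
  edges <- birth_edges(stree)
  t_deepest <- max(vapply(edges, `[[`, numeric(1), "t_max"))
  rows <- list()
  for (e in edges) {
    n <- rpois(1L, config$family_birth_rate * (e$t_max - e$t_min))
    if (n == 0L) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      birth_edge = e$label,
      t_birth = runif(n, e$t_min, e$t_max),
      present_species = paste(sort(e$species), collapse = ","))
  }
  fams <- data.table::rbindlist(rows)
  if (!nrow(fams)) stopf("no families born; raise family_birth_rate")
  data.table::setorder(fams, t_birth)
  fams[, family_id := sprintf("fam%04d", .I)]
  ## truth age group: the ladder applied to the true presence pattern
  truth <- lapply(strsplit(fams$present_species, ",", fixed = TRUE),
                  assign_age, stree = stree)
  fams[, true_age_group := vapply(truth, `[[`, character(1), "age_group")]
  fams[, true_rank := vapply(truth, `[[`, integer(1), "rank")]
  fams[, consensus_length := pmin(pmax(round(rlnorm(
    .N, log(config$init_consensus_length), 0.1)), 400L), 2500L)]
  fams[, class_superfamily := sample(
    superfamily_pool, .N, replace = TRUE,
    prob = c(rep(0.9 / 11, 11), 0.1))]
  frac <- pmin(fams$t_birth / t_deepest, 1)
  m <- config$meth_young_mean +
    (config$meth_ancient_mean - config$meth_young_mean) * frac
  conc <- config$meth_concentration_young +
    (config$meth_concentration_ancient - config$meth_concentration_young) *
    frac
  fams[, meth_fraction := pmin(pmax(
    rbeta(.N, m * conc, (1 - m) * conc), 0.002), 0.98)]
  fams[, sv_rate := config$base_activity *
    2^(-t_birth / config$activity_halflife) *
    exp(-config$suppression_beta * meth_fraction / config$meth_background) *
    rlnorm(.N, 0, config$activity_sd_log)]
  fams[, sequence := vapply(consensus_length, random_dna, character(1))]
  fams[, horizontal_transfer := FALSE]
  fams[]
}

## per (species, family) copy counts, insertion ages, lengths, windows
draw_copies <- function(config, fams) {
  sp_long <- fams[, .(species = strsplit(present_species, ",")[[1]]),
                  by = .(family_id, t_birth, consensus_length)]
  lam <- config$copy_burst + config$copy_saturation *
    (1 - 2^(-sp_long$t_birth / config$activity_halflife))
  sp_long[, n_copies := rpois(.N, lam)]
  copies <- sp_long[n_copies > 0L,
                    .(copy_i = seq_len(n_copies)),
                    by = .(species, family_id, t_birth, consensus_length)]
  n <- nrow(copies)
  burst_frac <- config$copy_burst /
    (config$copy_burst + config$copy_saturation)
  is_burst <- runif(n) < burst_frac
  rate <- log(2) / max(config$activity_halflife, 1e-9)
  u <- runif(n)
  s_ong <- -log(1 - u * (1 - exp(-rate * copies$t_birth))) / rate
  copies[, age := data.table::fifelse(
    is_burst, t_birth * runif(n, 0.85, 1), t_birth - s_ong)]
  copies[, length := pmin(pmax(round(
    consensus_length * 2^(-age / config$erosion_halflife) *
      rlnorm(.N, 0, 0.25)), 80L), consensus_length)]
  copies[, cons_start := floor(runif(.N) * (consensus_length - length + 1L))]
  copies[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  copies[, divergence := pmin(2 * config$mutation_rate * age, 0.6)]
  copies[, copy_id := sprintf("%s:%s:c%04d", family_id, species, copy_i)]
  copies[]
}

## spread copies over the genome, per species, with guaranteed > 5 kb
## between neighbouring copies so fragment linking is unambiguous
place_copies <- function(copies, config) {
  gl <- config$genome_layout
  L <- layout_lengths(gl)
  max_extra <- 3L * 320L          # fragment gap headroom
  guard <- 5200L
  out <- list()
  for (sp in sort(unique(copies$species))) {
    cp <- copies[species == sp]
    cp <- cp[sample.int(nrow(cp))]
    n <- nrow(cp)
    per_contig <- diff(round(seq(0, n, length.out = gl$n_contigs + 1L)))
    cp[, contig_i := rep(seq_len(gl$n_contigs), per_contig)]
    cp[, slot_i := seq_len(.N), by = contig_i]
    placed <- cp[, {
      pitch <- L$contig_len %/% (.N + 1L)
      span_max <- max(length) + max_extra
      if (pitch <= span_max + guard)
        stopf("genome too small for %d copies on one contig (%s)", .N, sp)
      anchor <- (slot_i - 1L) * pitch
      off <- floor(runif(.N) * pmax(pitch - (length + max_extra) - guard, 1))
      start <- anchor + off
      .(species = species, family_id = family_id, copy_id = copy_id,
        t_birth = t_birth, consensus_length = consensus_length,
        age = age, length = length, cons_start = cons_start,
        strand = strand, divergence = divergence,
        contig = sprintf("ctg%d", contig_i[1]), start = start)
    }, by = contig_i]
    placed[, contig_i := NULL]
    out[[sp]] <- placed
  }
  res <- data.table::rbindlist(out)
  res[, end := start + length]    # genomic span grows when fragmented
  res[]
}

## focal-species copies get real sequences (and alignments); other species
## keep their expected divergence only
realize_sequences <- function(placed, fams, config, focal) {
  seqs <- setNames(fams$sequence, fams$family_id)
  placed[, consensus_aln := NA_character_]
  placed[, copy_aln := NA_character_]
  idx <- which(placed$species == focal)
  if (length(idx)) {
    win <- substring(seqs[placed$family_id[idx]],
                     placed$cons_start[idx] + 1L,
                     placed$cons_start[idx] + placed$length[idx])
    mut <- vapply(seq_along(idx), function(k)
      mutate_sequence(win[k], placed$divergence[idx[k]]), character(1))
    placed[idx, consensus_aln := win]
    placed[idx, copy_aln := mut]
    ## realized divergence replaces the expected one for the focal species
    realized <- vapply(seq_along(idx), function(k) {
      a <- win[k]; b <- mut[k]
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) / nchar(a)
    }, numeric(1))
    placed[idx, divergence := realized]
  }
  placed
}

## split each copy into 1-3 fragments with small genomic gaps; consensus
## spans stay contiguous (descending along the genome on the minus strand)
fragment_copies <- function(placed, config) {
  p_geom <- 1 / config$fragment_mean
  out <- vector("list", nrow(placed))
  for (i in seq_len(nrow(placed))) {
    len <- placed$length[i]
    nf <- min(1L + rgeom(1L, p_geom), 3L, max(len %/% 60L, 1L))
    cuts <- if (nf > 1L) sort(sample(seq(40L, len - 40L), nf - 1L))
            else integer()
    lens <- diff(c(0L, cuts, len))
    gaps <- if (nf > 1L) sample(20:300, nf - 1L, replace = TRUE)
            else integer()
    gstart <- placed$start[i] + cumsum(c(0L, lens[-nf] + gaps))
    cstart <- placed$cons_start[i] + cumsum(c(0L, lens[-nf]))
    if (placed$strand[i] == "-") {
      ## genomic order carries descending consensus spans
      cstart <- placed$cons_start[i] + len - cumsum(lens)
    }
    out[[i]] <- data.table::data.table(
      species = placed$species[i],
      query_contig = placed$contig[i],
      query_start = gstart, query_end = gstart + lens,
      strand = placed$strand[i],
      family_id = placed$family_id[i],
      consensus_start = cstart, consensus_end = cstart + lens,
      score = round(lens * 2 * (1 - placed$divergence[i])),
      divergence_pct = round(placed$divergence[i] * 100, 2),
      deletion_pct = round(runif(1, 0, 2), 2),
      insertion_pct = round(runif(1, 0, 2), 2),
      copy_id = placed$copy_id[i])
  }
  hits <- data.table::rbindlist(out)
  ## classification column as RepeatMasker prints it
  data.table::setorder(hits, species, query_contig, query_start)
  hits[, hit_id := seq_len(.N), by = species]
  hits
}

draw_cpg <- function(placed, fams, config) {
  meth <- setNames(fams$meth_fraction, fams$family_id)
  gl <- config$genome_layout
  L <- layout_lengths(gl)
  out <- list()
  for (sp in sort(unique(placed$species))) {
    cp <- placed[species == sp]
    n_per <- rbinom(nrow(cp), cp$length, config$cpg_rate)
    rep_i <- rep(seq_len(nrow(cp)), n_per)
    pos_in <- floor(runif(length(rep_i)) * cp$length[rep_i])
    te <- data.table::data.table(
      contig = cp$contig[rep_i],
      pos = cp$start[rep_i] + pos_in,
      m = meth[cp$family_id[rep_i]])
    ## background sites rejected out of copy intervals
    nb <- config$background_cpg
    bg_global <- sample_outside_copies(nb, cp, L)
    gc <- global_to_contig(bg_global, gl)
    bg <- data.table::data.table(contig = gc$contig, pos = gc$pos,
                                 m = config$meth_background)
    x <- rbind(te, bg)
    x[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    x[, coverage := sample(5:60, .N, replace = TRUE)]
    methylated <- runif(nrow(x)) < x$m
    x[, meth_prob := data.table::fifelse(
      methylated, runif(.N, 0.801, 1), runif(.N, 0, 0.80))]
    x[, m := NULL]
    data.table::setorder(x, contig, pos)
    out[[sp]] <- cbind(species = sp, x)
  }
  data.table::rbindlist(out)
}

sample_outside_copies <- function(n, cp, L) {
  ## copies cover only a few percent of the genome; two rejection rounds
  ## suffice in practice, with a final overlap filter as a guarantee
  cand <- floor(runif(3L * n) * L$total)
  contig_i <- cand %/% L$contig_len + 1L
  local <- cand %% L$contig_len
  gr_cand <- GenomicRanges::GRanges(
    sprintf("ctg%d", contig_i), IRanges::IRanges(start = local + 1L, width = 1L))
  gr_cp <- GenomicRanges::GRanges(
    cp$contig, IRanges::IRanges(start = cp$start + 1L,
                                end = cp$end + 3L * 320L))
  bad <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gr_cand, gr_cp)))
  keep <- setdiff(seq_along(cand), bad)
  head(cand[keep], n)
}

draw_svs <- function(fams, config, focal) {
  gl <- config$genome_layout
  L <- layout_lengths(gl)
  in_focal <- grepl(paste0("(^|,)", focal, "(,|$)"), fams$present_species)
  ff <- fams[in_focal]
  k <- rpois(nrow(ff), ff$sv_rate)
  rep_i <- rep(seq_len(nrow(ff)), k)
  n <- length(rep_i)
  if (!n)
    return(data.table::data.table(
      sv_id = character(), contig = character(), position = integer(),
      sv_type = character(), length = integer(), sequence = character(),
      carriers = character(), family_id = character(), region = character()))
  ## rejection-sample insertion points against the exon penalty
  pos <- integer(n); got <- 0L
  while (got < n) {
    cand <- floor(runif(2L * (n - got)) * L$total)
    reg <- layout_region(cand, gl)
    acc <- runif(length(cand)) <
      ifelse(reg == "exon", config$exon_penalty, 1)
    cand <- cand[acc]
    take <- min(length(cand), n - got)
    if (take > 0L) pos[(got + 1L):(got + take)] <- cand[seq_len(take)]
    got <- got + take
  }
  fam_len <- ff$consensus_length[rep_i]
  sv_len <- pmax(60L, round(fam_len * runif(n, 0.5, 1)))
  sv_start <- floor(runif(n) * (fam_len - sv_len + 1L))
  age_sv <- runif(n, 0, 8)
  seqs <- vapply(seq_len(n), function(i) {
    w <- substring(ff$sequence[rep_i[i]], sv_start[i] + 1L,
                   sv_start[i] + sv_len[i])
    mutate_sequence(w, 2 * config$mutation_rate * age_sv[i])
  }, character(1))
  samples <- sprintf("%s_s%d", focal, seq_len(config$n_population_samples))
  carriers <- vapply(seq_len(n), function(i) {
    f <- runif(1, 0.1, 0.9)
    carry <- runif(length(samples)) < f
    if (!any(carry)) carry[sample.int(length(samples), 1L)] <- TRUE
    paste(samples[carry], collapse = ",")
  }, character(1))
  gc <- global_to_contig(pos, gl)
  svs <- data.table::data.table(
    sv_id = sprintf("sv%05d", seq_len(n)),
    contig = gc$contig, position = as.integer(gc$pos),
    sv_type = "INS", length = nchar(seqs), sequence = seqs,
    carriers = carriers,
    family_id = ff$family_id[rep_i],
    region = layout_region(pos, gl))
  data.table::setorder(svs, contig, position)
  svs[, sv_id := sprintf("sv%05d", seq_len(.N))]
  svs[]
}

#' Inject horizontal-transfer events into a simulated cohort
#'
#' Moves copies of `n_events` families into a species at least two chain
#' rings outside their native range (transfers into the adjacent ring are
#' phylogenetically invisible to a presence/absence ladder and are not
#' drawn). Transferred copies are recent: near-full-length, low divergence.
#' The families are flagged in the truth table; a presence/absence age
#' classifier should return "unknown" for them.
#'
#' @param cohort A `te_cohort` from [simulate_cohort()].
#' @param n_events Number of families to transfer (must not exceed the
#'   eligible families).
#' @param seed RNG seed for the event draw.
#' @return The modified cohort.
#' @export
inject_horizontal_transfer <- function(cohort, n_events, seed = 1L) {
  stopifnot(inherits(cohort, "te_cohort"))
  if (n_events == 0L) return(cohort)
  set.seed(seed)
  cohort <- unclass(cohort)
  cohort$families <- data.table::copy(cohort$families)
  cohort <- structure(cohort, class = "te_cohort")
  stree <- cohort$stree
  rings <- chain_rings(stree)
  fams <- cohort$families
  kmax <- vapply(strsplit(fams$present_species, ",", fixed = TRUE),
                 function(sp) max(which(vapply(
                   rings, function(r) any(sp %in% r), logical(1)))),
                 integer(1))
  eligible <- which(kmax <= length(rings) - 2L & !fams$horizontal_transfer)
  if (n_events > length(eligible))
    stopf("n_events (%d) exceeds eligible families (%d)", n_events,
          length(eligible))
  chosen <- sort(sample(eligible, n_events))
  cfg <- cohort$config
  new_rows <- list()
  for (i in chosen) {
    recipient_rings <- seq(kmax[i] + 2L, length(rings))
    recipient <- sample(unlist(rings[recipient_rings]), 1L)
    n_new <- 12L + rpois(1L, 4)
    len <- pmin(pmax(round(fams$consensus_length[i] *
                             rlnorm(n_new, 0, 0.1)), 80L),
                fams$consensus_length[i])
    new_rows[[length(new_rows) + 1L]] <- data.table::data.table(
      species = recipient, family_id = fams$family_id[i],
      copy_id = sprintf("%s:%s:ht%03d", fams$family_id[i], recipient,
                        seq_len(n_new)),
      t_birth = fams$t_birth[i],
      consensus_length = fams$consensus_length[i],
      age = runif(n_new, 0, 5), length = len,
      cons_start = floor(runif(n_new) *
                           (fams$consensus_length[i] - len + 1L)),
      strand = sample(c("+", "-"), n_new, replace = TRUE),
      divergence = 2 * cfg$mutation_rate * runif(n_new, 0, 5))
    fams[i, horizontal_transfer := TRUE]
    fams[i, present_species := paste(sort(unique(c(
      strsplit(present_species, ",")[[1]], recipient))), collapse = ",")]
    fams[i, true_age_group := "unknown"]
    fams[i, true_rank := NA_integer_]
  }
  add <- data.table::rbindlist(new_rows)
  ## re-place all copies of the affected species so spacing stays valid
  affected <- unique(add$species)
  keep_cols <- c("species", "family_id", "copy_id", "t_birth",
                 "consensus_length", "age", "length", "cons_start",
                 "strand", "divergence")
  base <- merge(cohort$copies,
                cohort$families[, .(family_id, t_birth, consensus_length)],
                by = "family_id")[, keep_cols, with = FALSE]
  pool <- rbind(base[species %in% affected], add)
  replaced <- place_copies(pool, cfg)
  replaced <- realize_sequences(replaced, fams, cfg, cohort$stree$focal)
  untouched <- cohort$copies[!species %in% affected]
  cohort$copies <- rbind(
    untouched,
    replaced[, .(species, family_id, copy_id, age, length, cons_start,
                 strand, contig, start, end, divergence)])
  new_hits <- fragment_copies(replaced, cfg)
  cohort$hits <- rbind(cohort$hits[!species %in% affected], new_hits)
  data.table::setorder(cohort$hits, species, query_contig, query_start)
  cohort$hits[, hit_id := seq_len(.N), by = species]
  ## CpG tables of affected species are regenerated over the new placement
  keep_cpg <- cohort$cpg[!species %in% affected]
  regen <- draw_cpg(replaced, fams, cfg)
  cohort$cpg <- rbind(keep_cpg, regen)
  cohort$copy_counts <- cohort$copies[, .(true_copy_number = .N),
                                      by = .(species, family_id)]
  cohort$families <- fams
  cohort
}

## ---- writers --------------------------------------------------------------

#' Write a simulated cohort to disk in the pipeline's external formats
#'
#' Per species: consensus FASTA (`<sp>_consensi.fa`, with
#' `consensus_lineage_divergence` applied outside the focal species),
#' RepeatMasker-style `.out` (`<sp>.out`), CpG table (`<sp>_cpg.tsv`) and
#' GFF3 gene models (`<sp>_genes.gff3`); for the focal species a
#' multi-sample VCF (`<focal>_svs.vcf`) and copy/consensus alignments
#' (`<focal>_alignments.tsv`); plus `tree.nwk`, `clades.yaml` and a
#' `truth/` directory with the ground-truth tables.
#'
#' @param cohort A `te_cohort`.
#' @param out_dir Output directory (created).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  cfg <- cohort$config
  focal <- cohort$stree$focal
  paths <- list()
  set.seed(child_seed(cfg$seed, 777L))
  species_all <- sort(unique(cohort$copies$species))
  for (sp in species_all) {
    fam_ids <- sort(unique(cohort$copies[species == sp, family_id]))
    lib <- cohort$families[family_id %in% fam_ids,
                           .(family_id, sequence, length = consensus_length,
                             class_superfamily)]
    data.table::setorder(lib, family_id)
    if (sp != focal && cfg$consensus_lineage_divergence > 0)
      lib[, sequence := vapply(sequence, mutate_sequence,
                               character(1),
                               divergence = cfg$consensus_lineage_divergence)]
    lib[, source_species := sp]
    p <- file.path(out_dir, paste0(sp, "_consensi.fa"))
    write_consensus_fasta(lib, p)
    paths[[paste0(sp, "_consensi")]] <- p

    h <- cohort$hits[species == sp]
    cls <- setNames(cohort$families$class_superfamily,
                    cohort$families$family_id)
    ht <- h[, .(query_contig, query_start, query_end, strand, family_id,
                class_superfamily = unname(cls[family_id]),
                consensus_start, consensus_end, score, divergence_pct,
                deletion_pct, insertion_pct, hit_id)]
    p <- file.path(out_dir, paste0(sp, ".out"))
    write_repeat_hits(ht, p, dialect = "rm_out")
    paths[[paste0(sp, "_out")]] <- p

    p <- file.path(out_dir, paste0(sp, "_cpg.tsv"))
    write_cpg_table(cohort$cpg[species == sp,
                               .(contig, pos, strand, coverage, meth_prob)],
                    p)
    paths[[paste0(sp, "_cpg")]] <- p

    p <- file.path(out_dir, paste0(sp, "_genes.gff3"))
    write_gene_models(cohort$genes[species == sp,
                                   .(gene_id, contig, strand, exon_start,
                                     exon_end)], p)
    paths[[paste0(sp, "_genes")]] <- p
  }
  samples <- sprintf("%s_s%d", focal, seq_len(cfg$n_population_samples))
  p <- file.path(out_dir, paste0(focal, "_svs.vcf"))
  write_sv_records(cohort$svs[, sv_cols, with = FALSE], p,
                   dialect = "vcf", samples = samples)
  paths$svs <- p
  p <- file.path(out_dir, paste0(focal, "_alignments.tsv"))
  data.table::fwrite(cohort$alignments, p, sep = "\t")
  paths$alignments <- p
  p <- file.path(out_dir, "tree.nwk")
  ape::write.tree(cohort$stree$tree, p)
  paths$tree <- p
  p <- file.path(out_dir, "clades.yaml")
  yaml::write_yaml(list(
    focal = cohort$stree$focal,
    steps = cohort$stree$chain,
    excluded = cohort$stree$excluded), p)
  paths$clades <- p
  truth_fam <- cohort$families[, .(family_id, birth_edge, t_birth,
                                   true_age_group, true_rank,
                                   present_species, consensus_length,
                                   class_superfamily, meth_fraction,
                                   sv_rate, horizontal_transfer)]
  p <- file.path(out_dir, "truth", "families.tsv")
  data.table::fwrite(truth_fam, p, sep = "\t")
  paths$truth_families <- p
  p <- file.path(out_dir, "truth", "copy_counts.tsv")
  data.table::fwrite(cohort$copy_counts, p, sep = "\t")
  paths$truth_copy_counts <- p
  p <- file.path(out_dir, "truth", "svs.tsv")
  data.table::fwrite(cohort$svs[, .(sv_id, family_id, region)], p,
                     sep = "\t")
  paths$truth_svs <- p
  p <- file.path(out_dir, "truth", "copies.tsv")
  data.table::fwrite(cohort$copies, p, sep = "\t")
  paths$truth_copies <- p
  invisible(paths)
}
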