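## Evolutionary age of TE families from presence/absence over a nested
## clade chain.
##
## Presence is called from the effective copy number (ECN = total copy bp /
## consensus length, present iff ECN > 5). The age group is read off a
## Dollo-style ladder: walking the chain outward from the focal species, a
## family's group is the outermost chain "ring" (species added at that step)
## holding a present species, and the pattern is consistent only if every
## ring between the innermost and outermost present rings also holds one.
## Inconsistent patterns (e.g. present only in the focal species and a deep
## in-group tip) violate the phylogeny, point at horizontal transfer, and
## are flagged "unknown".

#' Effective copy number of a TE family
#'
#' Total aligned length of all copies divided by the consensus length.
#'
#' @param total_copy_bp Summed copy bp.
#' @param consensus_length Consensus length in bp (> 0).
#' @return ECN, a non-negative real.
#' @export
effective_copy_number <- function(total_copy_bp, consensus_length) {
  if (any(consensus_length <= 0)) stopf("consensus_length must be > 0")
  total_copy_bp / consensus_length
}

#' Presence matrix from abundance and consensus lengths
#'
#' @param abundance Per (`species`, `family_id`) abundance
#'   ([abundance_table()]).
#' @param consensus_lengths `data.table` with `family_id`, `length`.
#' @param stree A `species_tree`; its `excluded` tips are dropped.
#' @param ecn_threshold Presence threshold; present iff ECN strictly exceeds
#'   it (default 5).
#' @return A `data.table` with `family_id`, `species`, `ecn`, `present`,
#'   containing every (family, non-excluded species) combination (absent
#'   species get ECN 0).
#' @export
presence_matrix <- function(abundance, consensus_lengths, stree,
                            ecn_threshold = 5) {
  keep_species <- setdiff(stree$chain[[length(stree$chain)]]$species,
                          stree$excluded)
  ab <- data.table::as.data.table(abundance)[species %in% keep_species]
  cl <- data.table::as.data.table(consensus_lengths)[, .(family_id, length)]
  full <- data.table::CJ(family_id = unique(ab$family_id),
                         species = keep_species)
  x <- merge(full, ab, by = c("family_id", "species"), all.x = TRUE)
  x[is.na(total_copy_bp), total_copy_bp := 0]
  x <- merge(x, cl, by = "family_id")
  x[, ecn := effective_copy_number(total_copy_bp, length)]
  x[, present := ecn > ecn_threshold]
  x[, .(family_id, species, ecn, present)]
}

#' Assign an evolutionary age group to one presence pattern
#'
#' @param present_species Character vector of species called present.
#' @param stree A `species_tree` with the nested clade chain.
#' @return A list with `age_group` (a chain step name, the sister-species
#'   label for a pure sister-specific pattern, or `"unknown"`) and `rank`
#'   (0 = focal-specific ... max = deepest step; sister-specific shares rank
#'   1 with the first non-focal step; `NA` for unknown).
#' @export
assign_age <- function(present_species, stree) {
  rings <- chain_rings(stree)
  present_species <- setdiff(present_species, stree$excluded)
  if (!length(present_species))
    stopf("family absent everywhere: no present species")
  occ <- which(vapply(rings, function(r) any(present_species %in% r),
                      logical(1)))
  stray <- setdiff(present_species, unlist(rings))
  if (length(stray))
    stopf("present species outside the clade chain: %s",
          paste(stray, collapse = ", "))
  kmin <- min(occ); kmax <- max(occ)
  if (!all(seq(kmin, kmax) %in% occ))
    return(list(age_group = "unknown", rank = NA_integer_))
  if (kmin == 2L && kmax == 2L) {
    ## pure sister-specific pattern: label by the sister ring itself
    return(list(age_group = paste0(rings[[2]], collapse = "+"), rank = 1L))
  }
  list(age_group = names(rings)[kmax], rank = kmax - 1L)
}

#' Assign age groups to every family in a presence matrix
#'
#' @param presence Output of [presence_matrix()].
#' @param stree A `species_tree`.
#' @return A `data.table` with `family_id`, `age_group`, `rank`. Families
#'   with no present species are dropped with a message (they cannot be
#'   aged).
#' @export
assign_ages <- function(presence, stree) {
  presence <- data.table::as.data.table(presence)
  fams <- presence[, .(sp = list(species[present])), by = family_id]
  empty <- fams[lengths(sp) == 0L, family_id]
  if (length(empty))
    message(sprintf("%d families absent everywhere at the ECN threshold; dropped",
                    length(empty)))
  fams <- fams[lengths(sp) > 0L]
  res <- lapply(fams$sp, assign_age, stree = stree)
  data.table::data.table(
    family_id = fams$family_id,
    age_group = vapply(res, `[[`, character(1), "age_group"),
    rank = vapply(res, `[[`, integer(1), "rank"))
}

#' Summarise age-group counts and fractions
#'
#' @param assignments Output of [assign_ages()].
#' @param stree A `species_tree` (fixes the group order).
#' @param merge_sister Fold a pure sister-specific group into the first
#'   non-focal chain step (default `TRUE`), matching focal-species summaries
#'   with one group per chain step.
#' @return A `data.table` with `age_group`, `rank`, `n`, `fraction`
#'   (fractions over classified, non-unknown families) plus an `unknown`
#'   row with `fraction = NA`.
#' @export
age_summary <- function(assignments, stree, merge_sister = TRUE) {
  x <- data.table::copy(data.table::as.data.table(assignments))
  rings <- chain_rings(stree)
  sister_label <- paste0(rings[[2]], collapse = "+")
  if (merge_sister)
    x[age_group == sister_label, age_group := names(rings)[2]]
  counts <- x[, .N, by = .(age_group)]
  lv <- c(names(rings), if (!merge_sister) sister_label, "unknown")
  counts <- counts[order(match(age_group, lv))]
  n_known <- counts[age_group != "unknown", sum(N)]
  counts[, fraction := ifelse(age_group == "unknown", NA_real_, N / n_known)]
  rk <- c(setNames(seq_along(rings) - 1L, names(rings)),
          setNames(1L, sister_label))
  counts[, rank := ifelse(age_group == "unknown", NA_integer_,
                          rk[age_group])]
  data.table::setnames(counts, "N", "n")
  counts[, .(age_group, rank, n, fraction)]
}
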