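## Non-redundant multi-species TE family catalog:
## size binning -> within-bin >=90% identity clustering -> longest-member
## representative; plus fragment linking into copies and abundance counting.

#' Read a TE consensus library from FASTA
#'
#' Headers follow the RepeatMasker convention `family_id#class/superfamily`;
#' anything after the first `#` is taken as the classification (families
#' without a `#` are recorded as `Unclassified`).
#'
#' @param path FASTA file.
#' @param species Optional species tag recorded in `source_species`.
#' @return A `data.table` with `family_id`, `sequence`, `length`,
#'   `class_superfamily`, `source_species`.
#' @export
read_consensus_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  cls <- ifelse(grepl("#", nm), sub("^[^#]*#", "", nm), "Unclassified")
  fam <- sub("#.*$", "", nm)
  data.table::data.table(
    family_id = fam, sequence = as.character(x),
    length = Biostrings::width(x),
    class_superfamily = cls, source_species = species)
}

#' Write a TE consensus library to FASTA
#'
#' @param families Catalog table as returned by [read_consensus_fasta()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(families, path) {
  seqs <- Biostrings::DNAStringSet(families$sequence)
  names(seqs) <- paste0(families$family_id, "#", families$class_superfamily)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

size_bin_breaks <- c(1, 500, 1000, 2000, 5000, 10000, 20000, Inf)

#' Bin consensus families by sequence length
#'
#' Bins are half-open below, so a boundary length (e.g. exactly 500 bp)
#' falls in the upper bin: `[1,500) [500,1e3) [1e3,2e3) [2e3,5e3) [5e3,1e4)
#' [1e4,2e4) [2e4,Inf)`.
#'
#' @param families Catalog table with `family_id` and `length`.
#' @return A named list mapping bin label to the `family_id`s it contains;
#'   empty bins are dropped.
#' @export
bin_by_size <- function(families) {
  if (!nrow(families)) return(list())
  if (any(families$length <= 0)) stopf("family lengths must be positive")
  labs <- c("[1,500)", "[500,1000)", "[1000,2000)", "[2000,5000)",
            "[5000,10000)", "[10000,20000)", "[20000,Inf)")
  b <- cut(families$length, breaks = size_bin_breaks, labels = labs,
           right = FALSE)
  out <- split(families$family_id, b, drop = TRUE)
  out[lengths(out) > 0]
}

#' Pairwise sequence identity (shorter fitted onto longer)
#'
#' Global alignment of the shorter sequence onto the longer
#' (`type = "global-local"`); identity is matches over alignment columns,
#' gaps counting as mismatch.
#'
#' @param a,b Nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

#' Cluster same-bin families by sequence identity
#'
#' Single-linkage clusters under pairwise identity >= `identity_threshold`
#' (see [seq_identity()]); mirrors the greedy transitive behaviour of
#' partial-matching clustering tools and is invariant to input order.
#'
#' @param families Catalog table (all members of one size bin).
#' @param identity_threshold Fraction in `(0, 1]`; default 0.90.
#' @param min_shared_kmers Pairs sharing fewer 11-mers than this skip
#'   alignment entirely (they cannot be near-identical).
#' @return A list of character vectors of `family_id`s, a partition of the
#'   input, each sorted, ordered by first member.
#' @export
cluster_families <- function(families, identity_threshold = 0.90,
                             min_shared_kmers = 5L) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stopf("identity_threshold must be in (0, 1]")
  n <- nrow(families)
  if (!n) return(list())
  ord <- order(families$family_id)
  ids <- families$family_id[ord]
  seqs <- families$sequence[ord]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1) {
    ki <- kmer_index(seqs)
    cand <- shared_kmer_pairs(ki, ki, min_shared_kmers)[q < s]
    ## a >= 90%-identical pair shares ~0.9^11 ~ 31% of its k-mers; a 5%
    ## floor rejects chance seed matches while keeping every pair that
    ## could possibly clear the identity threshold
    cand <- cand[n_shared >= pmax(
      min_shared_kmers,
      ceiling(0.05 * (pmin(nchar(seqs[q]), nchar(seqs[s])) - 10L)))]
    data.table::setorder(cand, q, s)
    for (r in seq_len(nrow(cand))) {
      i <- cand$q[r]; j <- cand$s[r]
      if (find(i) == find(j)) next
      ## equal-length pairs: the gap-free global alignment is exact
      ident <- if (nchar(seqs[i]) == nchar(seqs[j]))
        hamming_identity(seqs[i], seqs[j])
      else seq_identity(seqs[i], seqs[j])
      if (ident >= identity_threshold) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- split(ids, roots)
  cl <- lapply(cl, sort)
  unname(cl[order(vapply(cl, `[[`, character(1), 1L))])
}

#' Pick the representative family of a cluster
#'
#' The longest member wins; ties break to the lexicographically smallest
#' `family_id`. `source_species` becomes the union over members. The
#' representative keeps its own classification; if it is unclassified, the
#' classification of the first classified member (by id) is adopted.
#' Conflicting classifications among members are reported with a message.
#'
#' @param members Catalog table of the cluster's members.
#' @return A one-row catalog `data.table`.
#' @export
pick_representative <- function(members) {
  if (!nrow(members)) stopf("empty cluster")
  members <- data.table::as.data.table(members)
  data.table::setorder(members, -length, family_id)
  rep <- members[1]
  cls <- setdiff(unique(members$class_superfamily), "Unclassified")
  if (rep$class_superfamily == "Unclassified" && length(cls))
    rep[, class_superfamily := cls[1]]
  if (length(cls) > 1L)
    message(sprintf("cluster %s: conflicting classifications (%s); kept %s",
                    rep$family_id, paste(cls, collapse = ", "),
                    rep$class_superfamily))
  sp <- sort(unique(na.omit(unlist(
    strsplit(members$source_species, ",", fixed = TRUE)))))
  rep[, source_species := paste(sp, collapse = ",")]
  rep[]
}

#' Build the non-redundant catalog from a redundant multi-species library
#'
#' Convenience wrapper: [bin_by_size()] then [cluster_families()] per bin
#' then [pick_representative()] per cluster.
#'
#' @param families Redundant catalog table.
#' @inheritParams cluster_families
#' @return A list with `catalog` (one row per representative) and `clusters`
#'   (`data.table` mapping `family_id` to `representative_id`).
#' @export
build_catalog <- function(families, identity_threshold = 0.90) {
  families <- data.table::as.data.table(families)
  bins <- bin_by_size(families)
  reps <- list(); maps <- list()
  for (b in names(bins)) {
    sub <- families[family_id %in% bins[[b]]]
    cl <- cluster_families(sub, identity_threshold)
    for (members in cl) {
      r <- pick_representative(sub[family_id %in% members][
        !duplicated(family_id)])
      reps[[length(reps) + 1L]] <- r
      maps[[length(maps) + 1L]] <- data.table::data.table(
        family_id = members, representative_id = r$family_id, size_bin = b)
    }
  }
  list(catalog = data.table::rbindlist(reps),
       clusters = data.table::rbindlist(maps))
}

#' Link annotation fragments into TE copies
#'
#' Walks hits per (contig, family, strand) in genomic order and merges
#' consecutive fragments into one copy when the genomic gap is at most
#' `max_genomic_gap` and the consensus spans are collinear: on the plus
#' strand the next fragment must start at or after the previous fragment's
#' consensus end minus `consensus_tolerance` bp; mirrored on the minus
#' strand.
#'
#' @param hits Repeat-hit table sorted by (`query_contig`, `query_start`);
#'   unsorted input is an error.
#' @param max_genomic_gap Maximum genomic gap between fragments of one copy
#'   (bp, default 5000).
#' @param consensus_tolerance Allowed consensus-span overlap between
#'   consecutive fragments (bp, default 50).
#' @param species Species tag stamped onto the output.
#' @return A `data.table` of linked copies: `copy_id`, `family_id`,
#'   `species`, `contig`, `start`, `end` (0-based half-open), `strand`,
#'   `total_aligned_bp`, `n_hits`, `hit_ids` (comma-joined),
#'   `divergence_pct` (length-weighted mean over member hits).
#' @export
link_fragments <- function(hits, max_genomic_gap = 5000L,
                           consensus_tolerance = 50L,
                           species = NA_character_) {
  hits <- data.table::copy(data.table::as.data.table(hits))
  if (!nrow(hits)) return(empty_linked_copies())
  n <- nrow(hits)
  if (n > 1L) {
    same <- hits$query_contig[-n] == hits$query_contig[-1]
    ok <- !same | hits$query_start[-n] <= hits$query_start[-1]
    if (!all(ok))
      stopf("hits must be sorted by (query_contig, query_start)")
  }
  out <- hits[, link_one_group(.SD, .BY$strand, max_genomic_gap,
                               consensus_tolerance),
              by = .(query_contig, family_id, strand)]
  out[, species := species]
  out[, copy_id := sprintf("%s:%s:%d-%d", family_id, query_contig, start, end)]
  data.table::setnames(out, "query_contig", "contig")
  data.table::setcolorder(out, c("copy_id", "family_id", "species", "contig",
                                 "start", "end", "strand", "total_aligned_bp",
                                 "n_hits", "hit_ids", "divergence_pct"))
  data.table::setorder(out, contig, start)
  out[]
}

link_one_group <- function(sd, strand, max_gap, tol) {
  n <- nrow(sd)
  cid <- integer(n); cur <- 1L; cid[1] <- 1L
  if (n > 1) for (i in 2:n) {
    gap_ok <- sd$query_start[i] - sd$query_end[i - 1L] <= max_gap
    col_ok <- if (strand == "+")
      sd$consensus_start[i] >= sd$consensus_end[i - 1L] - tol
    else
      sd$consensus_end[i] <= sd$consensus_start[i - 1L] + tol
    if (!(gap_ok && col_ok)) cur <- cur + 1L
    cid[i] <- cur
  }
  sd <- data.table::copy(sd)
  sd[, cid := cid]
  sd[, {
    w <- query_end - query_start
    .(start = min(query_start), end = max(query_end),
      total_aligned_bp = sum(w), n_hits = .N,
      hit_ids = paste(hit_id, collapse = ","),
      divergence_pct = sum(divergence_pct * w) / sum(w))
  }, by = cid][, cid := NULL][]
}

empty_linked_copies <- function() {
  data.table::data.table(
    copy_id = character(), family_id = character(), species = character(),
    contig = character(), start = integer(), end = integer(),
    strand = character(), total_aligned_bp = integer(), n_hits = integer(),
    hit_ids = character(), divergence_pct = numeric())
}

#' Per-family abundance from linked copies
#'
#' @param copies Linked-copy table from [link_fragments()] (may span
#'   species).
#' @return A `data.table` with one row per (`species`, `family_id`):
#'   `copy_number` and `total_copy_bp` (sum of aligned bp).
#' @export
abundance_table <- function(copies) {
  copies <- data.table::as.data.table(copies)
  if (!nrow(copies))
    return(data.table::data.table(species = character(),
                                  family_id = character(),
                                  copy_number = integer(),
                                  total_copy_bp = numeric()))
  copies[, .(copy_number = .N,
             total_copy_bp = sum(as.numeric(total_aligned_bp))),
         by = .(species, family_id)]
}

#' Sum family abundances to superfamily level
#'
#' @param abundance Output of [abundance_table()].
#' @param classification `data.table` with `family_id`,
#'   `class_superfamily`; `Unclassified` families are dropped (they cannot
#'   be assigned a superfamily).
#' @return Per (`species`, `class_superfamily`) summed `copy_number`.
#' @export
superfamily_abundance <- function(abundance, classification) {
  x <- merge(data.table::as.data.table(abundance),
             data.table::as.data.table(classification)[
               , .(family_id, class_superfamily)],
             by = "family_id")
  x <- x[class_superfamily != "Unclassified"]
  x[, .(copy_number = sum(copy_number)), by = .(species, class_superfamily)]
}

#' Drop low-copy-number families
#'
#' Retains families with more than `min_copies - 1` copies (default: more
#' than 3), the copy-number floor applied before all downstream analyses to
#' limit spurious annotations.
#'
#' @param abundance Output of [abundance_table()].
#' @param min_copies Minimum retained copy number (default 4).
#' @return Filtered abundance table.
#' @export
filter_low_copy <- function(abundance, min_copies = 4L) {
  data.table::as.data.table(abundance)[copy_number >= min_copies]
}
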