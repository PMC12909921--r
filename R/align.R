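## Lightweight seed-and-extend alignment machinery.
##
## Candidate pairs are found through a k-mer index; each candidate is scored
## on its dominant seed diagonal with a maximal-scoring-subsegment (Kadane)
## extension under match 2 / mismatch -3. A full Smith-Waterman (Biostrings)
## is the fallback when the seed diagonal explains the pair poorly (e.g.
## indel-rich pairs). This mirrors the seed-diagonal design of the
## annotation tools the pipeline emulates while staying fast in pure R.

#' Positional k-mer index over a set of sequences
#'
#' @param seqs Character vector of nucleotide strings.
#' @param k k-mer size (default 11).
#' @return A `data.table` with `kmer`, `seq_i`, `pos` (0-based, first
#'   occurrence of each k-mer per sequence).
#' @export
kmer_index <- function(seqs, k = 11L) {
  out <- lapply(seq_along(seqs), function(i) {
    n <- nchar(seqs[i])
    if (n < k) return(NULL)
    km <- substring(seqs[i], 1:(n - k + 1L), k:n)
    first <- !duplicated(km)
    data.table::data.table(kmer = km[first], seq_i = i,
                           pos = which(first) - 1L)
  })
  data.table::rbindlist(out)
}

## (query_i, subject_i, n_shared) for pairs sharing >= min_shared k-mers
shared_kmer_pairs <- function(q_index, s_index, min_shared = 3L) {
  j <- merge(q_index[, .(kmer, q = seq_i, qpos = pos)],
             s_index[, .(kmer, s = seq_i, spos = pos)],
             by = "kmer", allow.cartesian = TRUE)
  if (!nrow(j))
    return(data.table::data.table(q = integer(), s = integer(),
                                  n_shared = integer()))
  j[, .(n_shared = .N), by = .(q, s)][n_shared >= min_shared]
}

## best-scoring contiguous subsegment of a +match/-mismatch vector,
## via prefix sums: max over e of prefix[e] - min prefix before e
best_segment <- function(is_match, match = 2, mismatch = -3) {
  v <- ifelse(is_match, match, mismatch)
  p <- cumsum(v)
  pre <- cummin(c(0, p[-length(p)]))
  gain <- p - pre
  e <- which.max(gain)
  if (gain[e] <= 0) return(NULL)
  s <- which(c(0, p)[seq_len(e)] == pre[e])[1]
  idx <- s:e
  list(score = gain[e], start = s, end = e,
       matches = sum(is_match[idx]), columns = length(idx))
}

## ungapped extension of a known diagonal (subject offset - query offset)
extend_diagonal <- function(query, subject, diag, k = 11L) {
  lq <- nchar(query); ls <- nchar(subject)
  q0 <- max(0L, -diag); q1 <- min(lq, ls - diag)
  if (q1 - q0 < k) return(NULL)
  a <- charToRaw(substring(query, q0 + 1L, q1))
  b <- charToRaw(substring(subject, q0 + diag + 1L, q1 + diag))
  seg <- best_segment(a == b)
  if (is.null(seg)) return(NULL)
  list(score = seg$score, identity = seg$matches / seg$columns,
       aligned = seg$columns)
}

#' Seed-diagonal local alignment of two sequences
#'
#' Finds the dominant diagonal among shared k-mers and extends it to the
#' maximal-scoring ungapped segment (match 2, mismatch -3). Returns `NULL`
#' when no k-mer seed exists.
#'
#' @param query,subject Nucleotide strings.
#' @param k Seed k-mer size (default 11).
#' @return A list `score`, `identity` (matches / columns), `aligned`
#'   (segment columns), or `NULL`.
#' @export
seed_local_align <- function(query, subject, k = 11L) {
  qi <- kmer_index(query, k)
  si <- kmer_index(subject, k)
  if (!nrow(qi) || !nrow(si)) return(NULL)
  j <- merge(qi[, .(kmer, qpos = pos)], si[, .(kmer, spos = pos)],
             by = "kmer")
  if (!nrow(j)) return(NULL)
  d <- j$spos - j$qpos
  diag <- as.integer(names(sort(table(d), decreasing = TRUE))[1])
  extend_diagonal(query, subject, diag, k)
}

## ungapped identity of two equal-length strings
hamming_identity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  sum(ra == rb) / length(ra)
}

## full local DP (Biostrings), match 2 / mismatch -3 / gap -5 per position
sw_local_align <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3),
    gapOpening = 0, gapExtension = 5)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln),
       identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0,
       aligned = cols)
}
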