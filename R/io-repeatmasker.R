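## Repeat annotation IO.
##
## External convention: RepeatMasker .out tables are 1-based inclusive, with
## minus-strand ("C") consensus coordinates written as (left) end begin.
## Internal convention: every interval in this package is 0-based half-open;
## the conversion happens exactly once, here.

rm_hit_cols <- c(
  "query_contig", "query_start", "query_end", "strand",
  "family_id", "class_superfamily",
  "consensus_start", "consensus_end",
  "score", "divergence_pct", "deletion_pct", "insertion_pct", "hit_id"
)

#' Read repeat annotation hits
#'
#' Parses a repeat annotation table into one row per alignment fragment
#' ("hit"). Two dialects are supported: `"rm_out"`, the standard 15-column
#' RepeatMasker `.out` table with its 3 header lines, and `"tsv"`, the
#' package's own tab-separated dump as written by [write_repeat_hits()].
#'
#' Coordinates are returned 0-based half-open on both the genome and the
#' family consensus. Minus-strand consensus coordinates (written
#' `(left) end begin` in `.out` files) are normalised so that
#' `consensus_start < consensus_end` always holds.
#'
#' @param path Path to the annotation file.
#' @param dialect `"rm_out"` or `"tsv"`.
#' @return A `data.table` with columns `query_contig`, `query_start`,
#'   `query_end`, `strand`, `family_id`, `class_superfamily`,
#'   `consensus_start`, `consensus_end`, `score`, `divergence_pct`,
#'   `deletion_pct`, `insertion_pct`, `hit_id`.
#' @seealso [write_repeat_hits()], [link_fragments()]
#' @export
read_repeat_hits <- function(path, dialect = c("rm_out", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "tsv") {
    hits <- data.table::fread(path, sep = "\t", header = TRUE,
                              colClasses = list(character = "query_contig"))
    missing <- setdiff(rm_hit_cols, names(hits))
    if (length(missing))
      stopf("tsv repeat table %s lacks columns: %s", path,
            paste(missing, collapse = ", "))
    return(validate_repeat_hits(hits[, rm_hit_cols, with = FALSE], path))
  }
  lines <- readLines(path)
  if (length(lines) < 3L)
    stopf("rm_out file %s has fewer than the 3 expected header lines", path)
  body <- lines[-(1:3)]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- which(keep) + 3L
  if (!length(body)) return(empty_repeat_hits())
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    ## optional trailing '*' marks an overlapping, lower-scoring hit
    if (length(f) == 16L && f[16] == "*") f <- f[1:15]
    if (length(f) != 15L)
      stopf("malformed rm_out row at line %d of %s (%d fields, expected 15)",
            lineno[i], path, length(f))
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    if (strand == "+") {
      cbeg <- f[12]; cend <- f[13]
    } else {
      ## (left) end begin
      cbeg <- f[14]; cend <- f[13]
    }
    num <- suppressWarnings(as.numeric(c(f[1:4], f[6], f[7], cbeg, cend, f[15])))
    if (anyNA(num))
      stopf("malformed rm_out row at line %d of %s: non-numeric field",
            lineno[i], path)
    g <- from1based(num[5], num[6])
    cc <- from1based(num[7], num[8])
    list(query_contig = f[5], query_start = g$start, query_end = g$end,
         strand = strand, family_id = f[10], class_superfamily = f[11],
         consensus_start = cc$start, consensus_end = cc$end,
         score = num[1], divergence_pct = num[2], deletion_pct = num[3],
         insertion_pct = num[4], hit_id = as.integer(num[9]))
  })
  validate_repeat_hits(data.table::rbindlist(rows), path)
}

empty_repeat_hits <- function() {
  data.table::data.table(
    query_contig = character(), query_start = integer(), query_end = integer(),
    strand = character(), family_id = character(),
    class_superfamily = character(),
    consensus_start = integer(), consensus_end = integer(),
    score = numeric(), divergence_pct = numeric(), deletion_pct = numeric(),
    insertion_pct = numeric(), hit_id = integer())
}

validate_repeat_hits <- function(hits, path = "<table>") {
  if (!nrow(hits)) return(hits[])
  bad <- which(hits$query_start >= hits$query_end |
                 hits$consensus_start >= hits$consensus_end |
                 hits$divergence_pct < 0 |
                 !hits$strand %in% c("+", "-"))
  if (length(bad))
    stopf("invalid repeat hit(s) in %s at row(s) %s", path,
          paste(head(bad, 5), collapse = ", "))
  hits[]
}

#' Write repeat annotation hits
#'
#' Inverse of [read_repeat_hits()]. The `"rm_out"` dialect re-applies the
#' 1-based inclusive convention and the minus-strand `(left) end begin`
#' consensus column order; `"tsv"` dumps the internal 0-based table as-is.
#' Unknown sequence lengths make the `(left)` columns unrecoverable, so they
#' are written as `(0)` placeholders (they are ignored on read).
#'
#' @param hits A repeat-hit `data.table` as returned by [read_repeat_hits()].
#' @param path Output path.
#' @param dialect `"rm_out"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_repeat_hits <- function(hits, path, dialect = c("rm_out", "tsv")) {
  dialect <- match.arg(dialect)
  hits <- validate_repeat_hits(data.table::as.data.table(hits))
  if (dialect == "tsv") {
    data.table::fwrite(hits, path, sep = "\t")
    return(invisible(path))
  }
  header <- c(
    paste("   SW   perc perc perc  query     position in query    ",
          "matching  repeat         position in repeat"),
    paste("score   div. del. ins.  sequence  begin end      (left)",
          "repeat    class/family   begin end   (left)  ID"),
    "")
  if (nrow(hits)) {
    g <- to1based(hits$query_start, hits$query_end)
    cc <- to1based(hits$consensus_start, hits$consensus_end)
    rep_cols <- ifelse(
      hits$strand == "+",
      sprintf("%d %d (0)", cc$start, cc$end),
      sprintf("(0) %d %d", cc$end, cc$start))
    rows <- sprintf(
      "%6.0f %6.1f %4.1f %4.1f  %s %d %d (0) %s %s %s %s %d",
      hits$score, hits$divergence_pct, hits$deletion_pct,
      hits$insertion_pct, hits$query_contig, g$start, g$end,
      ifelse(hits$strand == "+", "+", "C"),
      hits$family_id, hits$class_superfamily, rep_cols, hits$hit_id)
  } else rows <- character()
  writeLines(c(header, rows), path)
  invisible(path)
}
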