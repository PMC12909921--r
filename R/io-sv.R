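## Structural-variant record IO.
##
## A record is one multi-sample SV call: identifier, 0-based breakpoint,
## type, length, inserted sequence (INS), and the set of carrier samples.
## Carriers are stored as a comma-joined string in column `carriers` so the
## table stays a flat, round-trippable TSV.

sv_cols <- c("sv_id", "contig", "position", "sv_type", "length",
             "sequence", "carriers")

sv_carrier_count <- function(carriers) {
  n <- lengths(strsplit(carriers, ",", fixed = TRUE))
  n[!nzchar(carriers)] <- 0L
  n
}

#' Read structural-variant records
#'
#' Parses multi-sample SV calls from a minimal VCF 4.2 (only the `SVTYPE`
#' and `SVLEN` INFO keys and genotype presence are interpreted) or from the
#' package's own TSV dump. For VCF insertions whose ALT is a literal allele,
#' the inserted sequence is the ALT minus its leading anchor base. Carriers
#' are the samples whose genotype contains a non-reference allele.
#'
#' Breakpoints are returned 0-based: for an insertion anchored at VCF `POS`,
#' `position` is the half-open insertion point immediately after the anchor
#' base.
#'
#' @param path Path to the SV file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return A `data.table` with columns `sv_id`, `contig`, `position`,
#'   `sv_type`, `length`, `sequence`, `carriers`.
#' @export
read_sv_records <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "tsv") {
    x <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character =
                             c("contig", "sequence", "carriers")))
    missing <- setdiff(sv_cols, names(x))
    if (length(missing))
      stopf("SV table %s lacks columns: %s", path,
            paste(missing, collapse = ", "))
    x[is.na(sequence), sequence := ""]
    x[is.na(carriers), carriers := ""]
    return(validate_sv_records(x[, sv_cols, with = FALSE], path))
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) return(empty_sv_records())
  info <- fix[, "INFO"]
  svtype <- info_key(info, "SVTYPE")
  if (anyNA(svtype))
    stopf("VCF %s: missing SVTYPE INFO key at record(s) %s", path,
          paste(head(which(is.na(svtype)), 5), collapse = ", "))
  svlen <- suppressWarnings(abs(as.numeric(info_key(info, "SVLEN"))))
  alt <- fix[, "ALT"]
  seqs <- ifelse(svtype == "INS" & !grepl("^<", alt), substring(alt, 2), "")
  alt_len <- nchar(seqs)
  len <- ifelse(is.na(svlen), alt_len, svlen)
  mism <- which(!is.na(svlen) & svtype == "INS" & nzchar(seqs) &
                  alt_len != svlen)
  if (length(mism))
    warnf("VCF %s: SVLEN disagrees with ALT length at record(s) %s; SVLEN wins",
          path, paste(head(mism, 5), collapse = ", "))
  carriers <- rep("", nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) > 1L) {
    gt <- v@gt[, -1L, drop = FALSE]
    samples <- colnames(gt)
    carry <- matrix(grepl("[1-9]", sub(":.*", "", gt)),
                    nrow = nrow(gt), ncol = ncol(gt))
    carriers <- vapply(seq_len(nrow(gt)), function(i)
      paste(samples[carry[i, ]], collapse = ","), character(1))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("sv%06d", which(is.na(ids) | ids == "."))
  x <- data.table::data.table(
    sv_id = ids, contig = fix[, "CHROM"],
    position = as.integer(fix[, "POS"]),
    sv_type = svtype, length = as.integer(round(len)),
    sequence = seqs, carriers = carriers)
  validate_sv_records(x, path)
}

info_key <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- sub(paste0(".*", key, "="), "", m)
  out
}

empty_sv_records <- function() {
  data.table::data.table(
    sv_id = character(), contig = character(), position = integer(),
    sv_type = character(), length = integer(), sequence = character(),
    carriers = character())
}

validate_sv_records <- function(x, path = "<table>") {
  if (!nrow(x)) return(x[])
  bad <- which(x$sv_type != "BND" & (!is.finite(x$length) | x$length < 1))
  if (length(bad))
    stopf("SV table %s: non-BND record with length < 1 at row(s) %s",
          path, paste(head(bad, 5), collapse = ", "))
  if (!all(x$sv_type %in% c("INS", "DEL", "DUP", "INV", "BND")))
    stopf("SV table %s: unknown sv_type", path)
  x[]
}

#' Write structural-variant records
#'
#' The TSV dialect is the lossless inverse of [read_sv_records()]. The VCF
#' dialect writes a minimal VCF 4.2 with `SVTYPE`/`SVLEN` INFO keys and
#' `0/0` / `0/1` genotypes over the full sample roster.
#'
#' @param x SV `data.table` as returned by [read_sv_records()].
#' @param path Output path.
#' @param dialect `"vcf"` or `"tsv"`.
#' @param samples Character vector: the full sample roster (VCF dialect only).
#'   Defaults to the union of all carriers.
#' @return `path`, invisibly.
#' @export
write_sv_records <- function(x, path, dialect = c("vcf", "tsv"),
                             samples = NULL) {
  dialect <- match.arg(dialect)
  x <- validate_sv_records(data.table::as.data.table(x))
  if (dialect == "tsv") {
    data.table::fwrite(x[, sv_cols, with = FALSE], path, sep = "\t")
    return(invisible(path))
  }
  carrier_sets <- strsplit(x$carriers, ",", fixed = TRUE)
  if (is.null(samples))
    samples <- sort(unique(unlist(carrier_sets)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(x)), function(i) {
    alt <- if (x$sv_type[i] == "INS" && nzchar(x$sequence[i]))
      paste0("N", x$sequence[i]) else paste0("<", x$sv_type[i], ">")
    gts <- ifelse(samples %in% carrier_sets[[i]], "0/1", "0/0")
    paste(c(x$contig[i], x$position[i], x$sv_id[i], "N", alt, ".", "PASS",
            sprintf("SVTYPE=%s;SVLEN=%d", x$sv_type[i], x$length[i]),
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
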