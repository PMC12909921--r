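## Per-CpG methylation table IO.
##
## Documented header: contig  pos  strand  coverage  meth_prob
## `pos` is the 0-based position of the CpG cytosine on the annotated strand.
## Records on opposite strands of one CpG dinucleotide are kept distinct (no
## strand collapsing): the upstream caller's convention varies in the wild,
## and collapsing is not reversible.

cpg_cols <- c("contig", "pos", "strand", "coverage", "meth_prob")

#' Read a per-CpG methylation table
#'
#' @param path TSV file with header `contig pos strand coverage meth_prob`.
#' @return A `data.table` with those columns; `pos` 0-based, `strand` one of
#'   `+`, `-`, `.`, `coverage` a non-negative integer read count, `meth_prob`
#'   the per-site 5mC probability in `[0, 1]`.
#' @export
read_cpg_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = "contig"))
  missing <- setdiff(cpg_cols, names(x))
  if (length(missing))
    stopf("CpG table %s lacks columns: %s", path,
          paste(missing, collapse = ", "))
  x <- x[, cpg_cols, with = FALSE]
  validate_cpg_table(x, path)
}

validate_cpg_table <- function(x, path = "<table>") {
  if (!nrow(x)) return(x[])
  bad_cov <- which(!is.finite(x$coverage) | x$coverage < 0)
  if (length(bad_cov))
    stopf("CpG table %s: negative or missing coverage at data row(s) %s",
          path, paste(head(bad_cov, 5), collapse = ", "))
  bad_p <- which(!is.finite(x$meth_prob) | x$meth_prob < 0 | x$meth_prob > 1)
  if (length(bad_p))
    stopf("CpG table %s: meth_prob outside [0, 1] at data row(s) %s",
          path, paste(head(bad_p, 5), collapse = ", "))
  bad_s <- which(!x$strand %in% c("+", "-", "."))
  if (length(bad_s))
    stopf("CpG table %s: invalid strand at data row(s) %s",
          path, paste(head(bad_s, 5), collapse = ", "))
  x[]
}

#' Write a per-CpG methylation table
#'
#' @param x `data.table` as returned by [read_cpg_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(x, path) {
  x <- validate_cpg_table(data.table::as.data.table(x)[, cpg_cols, with = FALSE])
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
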