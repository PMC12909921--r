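## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check that a value is a single finite number
#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

## 1-based inclusive -> 0-based half-open, applied exactly once at parse
## boundaries (RepeatMasker .out, GFF3, VCF POS).
from1based <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

to1based <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

## Deterministic child seed derivation, kept below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k)) %% 2147483587L
}

random_dna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
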