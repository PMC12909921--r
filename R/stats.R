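## The statistical battery: transforms, ANCOVA, congruence permutation test,
## exact binomial enrichment, group tests, correlations, ordination.

#' log10(x + 1) abundance transform
#'
#' @param values Non-negative numeric vector.
#' @return `log10(values + 1)`.
#' @export
transform_abundance <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stopf("negative abundance values")
  log10(values + 1)
}

#' ANCOVA of a response on methylation, age and their interaction
#'
#' Fits `response ~ methylation * age` by least squares and reports the
#' sequential (Type I) analysis-of-variance table in the formula order
#' methylation, age, methylation:age — the convention under which, with
#' n = 2144 families and 5 age levels, the term dfs are (1, 4, 4) and the
#' residual df 2134.
#'
#' @param response Numeric response (already transformed, e.g.
#'   [transform_abundance()]).
#' @param methylation Numeric covariate.
#' @param age Factor (or coercible) with at least 2 observed levels.
#' @return A list: `table` (`data.table` of term/df/sum_sq/F/p),
#'   `residual_df`, `n`, `coefficients`.
#' @export
fit_ancova <- function(response, methylation, age) {
  age <- droplevels(as.factor(age))
  cc <- complete.cases(response, methylation, age)
  d <- data.frame(response = response[cc], methylation = methylation[cc],
                  age = droplevels(age[cc]))
  if (nlevels(d$age) < 2L) stopf("age needs at least 2 observed levels")
  small <- names(which(table(d$age) < 2L))
  if (length(small))
    stopf("age level(s) with fewer than 2 observations: %s",
          paste(small, collapse = ", "))
  fit <- lm(response ~ methylation * age, data = d)
  an <- suppressWarnings(anova(fit))  # degenerate fits warn harmlessly
  tab <- data.table::data.table(
    term = rownames(an), df = an$Df, sum_sq = an$`Sum Sq`,
    f = an$`F value`, p = an$`Pr(>F)`)
  ## a constant response has zero SS everywhere (up to floating-point dust);
  ## report F = 0 rather than noise ratios or 0/0
  if (var(d$response) == 0 || all(tab$sum_sq < 1e-20))
    tab[, `:=`(f = 0, p = 1)]
  tab[is.nan(f), `:=`(f = 0, p = 1)]
  list(table = tab,
       residual_df = an["Residuals", "Df"],
       n = nrow(d),
       coefficients = coef(fit))
}

#' Dendrogram congruence by permutation
#'
#' Hierarchically clusters the rows of two matrices (Euclidean distance,
#' complete linkage), takes the Pearson correlation of the two cophenetic
#' distance matrices as the congruence statistic, and builds the null by
#' permuting the leaf labels of the second dendrogram;
#' `p = (1 + #\{perm >= observed\}) / (n_permutation + 1)`.
#'
#' @param matrix_a,matrix_b Numeric matrices with matching, named rows
#'   (>= 3), already preprocessed (e.g. log10+1 abundance, within-row
#'   standardised methylation).
#' @param n_permutation Number of label permutations (default 1000).
#' @param seed Optional RNG seed for the permutations.
#' @return A list: `statistic`, `p`, `n_permutation`.
#' @export
dendrogram_congruence <- function(matrix_a, matrix_b, n_permutation = 1000L,
                                  seed = NULL) {
  if (nrow(matrix_a) < 3L) stopf("need at least 3 rows (genomes)")
  if (!is.null(rownames(matrix_a)) && !is.null(rownames(matrix_b))) {
    if (!setequal(rownames(matrix_a), rownames(matrix_b)))
      stopf("row labels of the two matrices differ")
    matrix_b <- matrix_b[rownames(matrix_a), , drop = FALSE]
  } else if (nrow(matrix_a) != nrow(matrix_b)) {
    stopf("matrices must have the same rows")
  }
  if (!is.null(seed)) set.seed(seed)
  ca <- as.matrix(cophenetic(hclust(dist(matrix_a), method = "complete")))
  cb <- as.matrix(cophenetic(hclust(dist(matrix_b), method = "complete")))
  ord <- rownames(matrix_a) %||% seq_len(nrow(matrix_a))
  ca <- ca[ord, ord]; cb <- cb[ord, ord]
  lower <- lower.tri(ca)
  obs <- cor(ca[lower], cb[lower])
  n <- nrow(ca)
  ## permuting leaf labels of dendrogram b == permuting rows+cols of its
  ## cophenetic matrix, so the trees are built once
  perm_ge <- 0L
  for (i in seq_len(n_permutation)) {
    pp <- sample.int(n)
    cp <- cb[pp, pp]
    if (cor(ca[lower], cp[lower]) >= obs) perm_ge <- perm_ge + 1L
  }
  list(statistic = obs, p = (1 + perm_ge) / (n_permutation + 1),
       n_permutation = n_permutation)
}

#' Exact two-sided binomial enrichment test
#'
#' Two-sided exact p as the total probability of outcomes no more likely
#' than the observed count (point-probability method), with the
#' Clopper-Pearson 95% confidence interval on the proportion.
#'
#' @param k Successes.
#' @param n Trials.
#' @param p0 Background proportion in `(0, 1)`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `k`, `n`, `p0`, `proportion`, `p`, `conf_int`.
#' @export
enrichment_binomial <- function(k, n, p0, conf_level = 0.95) {
  if (p0 <= 0 || p0 >= 1) stopf("p0 must be inside (0, 1)")
  if (k < 0 || k > n) stopf("need 0 <= k <= n")
  dens <- dbinom(0:n, n, p0)
  ## tolerance guards against ties broken by floating-point noise
  p <- sum(dens[dens <= dens[k + 1L] * (1 + 1e-7)])
  p <- min(1, p)
  alpha <- 1 - conf_level
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  list(k = k, n = n, p0 = p0, proportion = k / n, p = p,
       conf_int = c(lo, hi))
}

#' Two-group and 2x2 tests
#'
#' Wilcoxon rank-sum with midrank tie handling (two-sided), and Fisher's
#' exact test on a 2x2 table reporting both the sample (cross-product) odds
#' ratio — the convention that reproduces printed odds ratios — and the
#' conditional-MLE odds ratio from the exact test.
#'
#' @param x,y Two numeric samples (rank-sum), or `x` a 2x2 matrix (Fisher)
#'   with `y` omitted.
#' @return For two samples: list `W`, `p`. For a 2x2 table: list
#'   `odds_ratio` (sample), `odds_ratio_cmle`, `p`, `conf_int`.
#' @export
group_tests <- function(x, y = NULL) {
  if (is.matrix(x)) {
    if (!all(dim(x) == 2L)) stopf("Fisher test needs a 2x2 table")
    ft <- fisher.test(x)
    sample_or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
    return(list(odds_ratio = sample_or,
                odds_ratio_cmle = unname(ft$estimate),
                p = ft$p.value, conf_int = as.numeric(ft$conf.int)))
  }
  if (is.null(y) || !length(x) || !length(y)) stopf("two non-empty samples required")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Spearman correlation with exact small-sample p
#'
#' Midrank-based Spearman rho. For n <= 30 without ties the p-value is the
#' exact permutation probability; otherwise the t approximation on
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method Only `"spearman"`.
#' @return A list: `rho`, `p`, `n`, `method` (`"exact"` or
#'   `"t-approximation"`); `rho` is `NA` for constant input.
#' @export
correlation <- function(x, y, method = "spearman") {
  stopifnot(method == "spearman")
  cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 30L && !ties) {
    p <- cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n,
       method = "t-approximation")
}

#' Principal component analysis of genome-by-superfamily matrices
#'
#' `mode = "abundance"` applies log10+1; `mode = "methylation"` standardises
#' within each genome (row). PCA is centred, unscaled, via SVD; each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param matrix Genomes x features numeric matrix (>= 3 rows).
#' @param mode `"abundance"`, `"methylation"`, or `"none"` (preprocessed
#'   input).
#' @return A list: `scores`, `loadings`, `explained` (variance fractions).
#' @export
ordination <- function(matrix, mode = c("abundance", "methylation", "none")) {
  mode <- match.arg(mode)
  if (nrow(matrix) < 3L) stopf("need at least 3 genomes (rows)")
  x <- switch(mode,
    abundance = transform_abundance(matrix),
    methylation = standardize_rows(matrix),
    none = matrix)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Standardise a matrix within each row
#'
#' Centres and scales each row to zero mean / unit variance, the
#' within-genome standardisation applied to methylation levels before
#' ordination and clustering (sequencing depth shifts whole genomes).
#' Zero-variance rows become all-zero.
#'
#' @param matrix Numeric matrix.
#' @return The row-standardised matrix.
#' @export
standardize_rows <- function(matrix) {
  t(apply(matrix, 1, function(r) {
    s <- sd(r)
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
}
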