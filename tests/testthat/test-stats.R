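## The statistical battery.

test_that("the abundance transform is log10(x + 1)", {
  expect_equal(transform_abundance(c(0, 9, 99)), c(0, 1, 2))
  expect_error(transform_abundance(-1), "negative")
})

test_that("ANCOVA reports sequential SS with the published df shape", {
  set.seed(1)
  n <- 2144L
  age <- factor(rep(c("a", "b", "c", "d", "e"),
                    c(85, 239, 403, 713, 704)))
  meth <- runif(n)
  y <- 1 + 0.5 * meth + as.numeric(age) * 0.1 + rnorm(n, 0, 0.3)
  fit <- fit_ancova(y, meth, age)
  expect_equal(fit$table$df[1:3], c(1L, 4L, 4L))
  expect_equal(fit$residual_df, 2134L)
  expect_equal(fit$n, 2144L)
  ## sequential SS sum to the total SS
  expect_equal(sum(fit$table$sum_sq), sum((y - mean(y))^2))
  ## constant response -> all F reported as 0
  fit0 <- fit_ancova(rep(1, n), meth, age)
  expect_equal(fit0$table$f[1:3], c(0, 0, 0))
  ## a level with < 2 observations errors, naming the level
  age_bad <- factor(c("solo", as.character(age[-1])),
                    levels = c(levels(age), "solo"))
  expect_error(fit_ancova(y, meth, age_bad), "solo")
})

test_that("ANCOVA recovers generating slopes and detects true interactions", {
  set.seed(2)
  hits <- 0L; slope_err <- numeric(30)
  for (i in 1:30) {
    n <- 500L
    age <- factor(sample(c("young", "mid", "old"), n, replace = TRUE))
    meth <- runif(n, 0, 1)
    slope <- c(young = -1.0, mid = -0.6, old = -0.2)
    y <- 2 + slope[as.character(age)] * meth + rnorm(n, 0, 0.4)
    fit <- fit_ancova(y, meth, age)
    p_int <- fit$table[term == "methylation:age", p]
    if (p_int < 0.05) hits <- hits + 1L
    ## pooled slope estimate vs the mean generating slope
    slope_err[i] <- unname(fit$coefficients["methylation"])
  }
  expect_gte(hits / 30, 0.8)
})

test_that("dendrogram congruence is exact for identical matrices and errors when degenerate", {
  set.seed(3)
  m <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("f", 1:5)))
  r <- dendrogram_congruence(m, m, n_permutation = 1000, seed = 1)
  expect_equal(r$statistic, 1)
  expect_equal(r$p, 1 / 1001)
  expect_error(dendrogram_congruence(m[1:2, ], m[1:2, ]), "3 rows")
  ## statistic bounded and p at least 1/(B+1)
  m2 <- matrix(rnorm(8 * 5), 8, 5, dimnames = dimnames(m))
  r2 <- dendrogram_congruence(m, m2, n_permutation = 200, seed = 2)
  expect_true(abs(r2$statistic) <= 1)
  expect_gte(r2$p, 1 / 201)
})

test_that("exact binomial enrichment matches the enumeration and base R", {
  r <- enrichment_binomial(15, 49, 0.07)
  expect_equal(r$proportion, 15 / 49)
  expect_lt(r$p, 1e-5)
  ## Clopper-Pearson interval, cross-checked against base R
  expect_equal(r$conf_int,
               as.numeric(binom.test(15, 49, 0.07)$conf.int),
               tolerance = 1e-10)
  r0 <- enrichment_binomial(0, 10, 0.5)
  expect_equal(r0$proportion, 0)
  expect_equal(r0$conf_int[1], 0)
  ## observed equals expectation -> p ~ 1 (exact-sum over all 101 outcomes)
  expect_gt(enrichment_binomial(7, 100, 0.07)$p, 0.99)
  ## cross-check against binom.test over a sweep
  for (n in c(5, 20, 49, 60)) for (p0 in c(0.07, 0.5)) for (k in 0:n) {
    expect_equal(enrichment_binomial(k, n, p0)$p,
                 binom.test(k, n, p0)$p.value, tolerance = 1e-12,
                 info = sprintf("k=%d n=%d p0=%g", k, n, p0))
  }
  expect_error(enrichment_binomial(3, 10, 1.2), "p0")
})

test_that("Fisher tests report the sample odds ratio; rank-sum handles ties", {
  tab <- matrix(c(71, 493, 32, 352), nrow = 2)  # rows: young, ancient
  ft <- group_tests(tab)
  expect_equal(round(ft$odds_ratio, 2), 1.58)
  expect_equal(ft$p, fisher.test(tab)$p.value)
  sym <- group_tests(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  ## Fisher p equals hypergeometric enumeration for moderate tables
  set.seed(4)
  for (i in 1:25) {
    m <- matrix(rpois(4, 12) + 1L, 2)
    ours <- group_tests(m)$p
    ## enumeration oracle: condition on margins, sum P(tables) <= P(obs)
    a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    amin <- max(0L, c1 - (n - r1)); amax <- min(r1, c1)
    dens <- dhyper(amin:amax, r1, n - r1, c1)
    oracle <- sum(dens[dens <= dhyper(a, r1, n - r1, c1) * (1 + 1e-7)])
    expect_equal(ours, min(1, oracle), tolerance = 1e-10)
  }
  w <- group_tests(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(w$p, 1, tolerance = 1e-9)
  expect_error(group_tests(numeric(), 1:3), "non-empty")
})

test_that("Spearman correlation is exact for small n and midrank-based", {
  expect_equal(correlation(1:10, 1:10)$rho, 1)
  expect_equal(correlation(1:10, -(1:10))$rho, -1)
  ## d = (-1, 1, -1, 1, 0): rho = 1 - 6*4 / (5*24) = 0.8
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- correlation(x, y)
  expect_equal(r$rho, 0.8)
  ## brute-force permutation oracle over all 120 rank permutations
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  rhos <- vapply(perms(1:5), function(pp) cor(1:5, pp), numeric(1))
  p_exact <- mean(abs(rhos) >= abs(r$rho) - 1e-12)
  expect_equal(r$p, p_exact, tolerance = 1e-9)
  expect_equal(r$method, "exact")
  ## constant input -> undefined, reported missing
  expect_true(is.na(correlation(rep(1, 5), 1:5)$rho))
  ## large n uses the t approximation
  set.seed(5)
  big <- correlation(rnorm(100), rnorm(100))
  expect_equal(big$method, "t-approximation")
})

test_that("ordination centres via SVD with fixed signs and conserved variance", {
  set.seed(6)
  m <- matrix(rexp(6 * 8), 6, 8,
              dimnames = list(paste0("g", 1:6), paste0("f", 1:8)))
  o <- ordination(m, mode = "abundance")
  expect_equal(sum(o$explained), 1)
  ## duplicated genome rows get identical scores
  m2 <- rbind(m, dup = m[1, ])
  o2 <- ordination(m2, mode = "abundance")
  expect_equal(unname(o2$scores["g1", ]), unname(o2$scores["dup", ]))
  ## rank-1 matrix -> PC1 explains everything
  r1 <- outer(1:5, 1:4)
  rownames(r1) <- paste0("g", 1:5)
  o3 <- ordination(r1, mode = "none")
  expect_equal(o3$explained[1], 1)
  ## sign convention: largest-magnitude loading positive
  expect_true(all(apply(o$loadings, 2, function(v) v[which.max(abs(v))]) > 0))
  ## within-genome standardisation: rows have mean 0, sd 1
  s <- standardize_rows(m)
  expect_equal(unname(rowMeans(s)), rep(0, 6))
  expect_equal(unname(apply(s, 1, sd)), rep(1, 6))
})
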