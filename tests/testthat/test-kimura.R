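## CpG-aware K2P divergence and KD landscape classification.

test_that("site-pattern counting handles transitions, transversions and CpG weighting", {
  L <- 100L
  cons <- strrep("A", L)
  ## 10 transitions (A->G), 5 transversions (A->C), no CpG in consensus
  copy <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", L - 15))
  pat <- count_site_patterns(cons, copy)
  expect_equal(pat$n_sites, 100)
  expect_equal(pat$p, 0.10)
  expect_equal(pat$q, 0.05)
  ## identical sequences
  pat0 <- count_site_patterns(cons, cons)
  expect_equal(unlist(pat0[c("n_sites", "p_count", "q_count")]),
               c(n_sites = 100, p_count = 0, q_count = 0))
  ## CpG mask: C of the CG in ACGT, transition C->T weighted 1/10
  pat_cpg <- count_site_patterns("ACGT", "ATGT")
  expect_equal(pat_cpg$p_count, 0.1)
  expect_equal(pat_cpg$n_sites, 4)
  ## w_cpg = 1 recovers the unweighted count
  expect_equal(count_site_patterns("ACGT", "ATGT", w_cpg = 1)$p_count, 1)
  ## the mask survives gaps between C and G
  pat_gap <- count_site_patterns("AC-GT", "AT-GT")
  expect_equal(pat_gap$p_count, 0.1)
  expect_equal(pat_gap$n_sites, 4)
  ## ambiguity codes skip the column entirely
  patN <- count_site_patterns("ANGT", "AGGT")
  expect_equal(patN$n_sites, 3)
  expect_equal(patN$p_count, 0)
  expect_error(count_site_patterns("ACG", "AC"), "length mismatch")
})

test_that("kimura2p matches the closed form and saturates outside its domain", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.10, 0.05), 17.02, tolerance = 1e-3)
  expect_true(is.na(kimura2p(0.45, 0.10)))  # 1 - 2p - q = 0
  expect_true(is.na(kimura2p(0.2, 0.5)))    # 1 - 2q = 0
  ## independent evaluation on a grid
  grid <- expand.grid(p = seq(0.01, 0.25, length.out = 10),
                      q = seq(0.01, 0.15, length.out = 10))
  direct <- 100 * (-0.5 * log((1 - 2 * grid$p - grid$q) *
                                sqrt(1 - 2 * grid$q)))
  expect_equal(kimura2p(grid$p, grid$q), direct)
  ## monotonicity in p and in q
  kd_mat <- matrix(kimura2p(grid$p, grid$q), nrow = 10)
  expect_true(all(apply(kd_mat, 2, diff) > 0))
  expect_true(all(apply(kd_mat, 1, diff) > 0))
})

test_that("kimura2p recovers simulated divergence under the K2P process", {
  ## simulate per-site substitutions with 2:1 transition:transversion odds,
  ## estimate p and q, and recover the generating distance within 3 sigma
  set.seed(101)
  L <- 2000L
  true_kd <- c(5, 15, 25)
  for (kd in true_kd) {
    ## invert: choose (p, q) with p = 2q consistent with this KD
    f <- function(q) kimura2p(2 * q, q) - kd
    q <- uniroot(f, c(1e-6, 0.19))$root
    p <- 2 * q
    reps <- replicate(40, {
      bases <- c("A", "C", "G", "T")
      cons <- sample(bases, L, replace = TRUE)
      r <- runif(L)
      ts_map <- c(A = "G", G = "A", C = "T", T = "C")
      copy <- cons
      is_ts <- r < p
      is_tv <- r >= p & r < p + q
      copy[is_ts] <- ts_map[cons[is_ts]]
      copy[is_tv] <- vapply(cons[is_tv], function(b)
        sample(setdiff(bases, c(b, ts_map[b])), 1), character(1))
      pat <- count_site_patterns(paste(cons, collapse = ""),
                                 paste(copy, collapse = ""), w_cpg = 1)
      kimura2p(pat$p, pat$q)
    })
    expect_lt(abs(mean(reps) - kd), 3 * sd(reps) / sqrt(length(reps)))
  }
})

test_that("KD histograms partition finite values and landscapes classify by mode position", {
  set.seed(33)
  recent <- pmax(rnorm(200, 5, 2), 0)
  h <- kd_histogram(recent)
  expect_equal(sum(h), 200L)
  expect_equal(classify_kd_profile(h)$shape_class, "recent_expansion")
  remnant <- rnorm(200, 28, 4)
  expect_equal(classify_kd_profile(kd_histogram(remnant))$shape_class,
               "remnant")
  mixed <- c(rnorm(100, 5, 2), rnorm(100, 28, 4))
  expect_equal(classify_kd_profile(kd_histogram(mixed))$shape_class,
               "mixed")
  ## too few copies -> unresolved
  expect_equal(classify_kd_profile(kd_histogram(rnorm(10, 5, 2)))$shape_class,
               "unresolved")
  ## single mode between the cuts -> unresolved
  expect_equal(classify_kd_profile(kd_histogram(rnorm(200, 15, 2)))$shape_class,
               "unresolved")
  ## values at or above 50 are clamped, NA (saturated) dropped
  expect_equal(sum(kd_histogram(c(55, 49.5, NA, 3))), 3L)
})

test_that("copy_kd aggregates per-copy distances per family", {
  aln <- data.table(
    family_id = c("f1", "f1"), copy_id = c("c1", "c2"),
    consensus_aln = c("AAAAAAAAAA", "AAAAAAAAAA"),
    copy_aln = c("AAAAAAAAAA", "GGAAAAAAAA"))
  kd <- copy_kd(aln)
  expect_equal(kd$kd[1], 0)
  expect_gt(kd$kd[2], 0)
  prof <- kd_profiles(kd, min_copies = 1L)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$n_copies, 2L)
})
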