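## CpG site calling and per-family / superfamily aggregation.

test_that("site calling is inclusive on coverage 10-50 and strict on prob 0.80", {
  rec <- data.table(
    contig = "c", pos = 1:7 * 10L, strand = "+",
    coverage = c(30L, 9L, 30L, 10L, 50L, 51L, 0L),
    meth_prob = c(0.90, 0.99, 0.80, 0.81, 0.801, 0.9, 0.5))
  st <- call_sites(rec)$status
  expect_equal(st, c("methylated", "excluded", "unmethylated",
                     "methylated", "methylated", "excluded", "excluded"))
  ## partition conservation
  expect_equal(sum(table(st)), nrow(rec))
})

test_that("genome background is methylated over evaluable sites", {
  rec <- data.table(contig = "c", pos = seq_len(110) * 2L, strand = "+",
                    coverage = c(rep(30L, 100), rep(5L, 10)),
                    meth_prob = c(rep(0.9, 8), rep(0.1, 92), rep(0.9, 10)))
  calls <- call_sites(rec)
  expect_equal(genome_background(calls), 0.08)
  all_meth <- call_sites(data.table(contig = "c", pos = 1:4, strand = "+",
                                    coverage = 30L, meth_prob = 0.99))
  expect_equal(genome_background(all_meth), 1)
  none <- call_sites(data.table(contig = "c", pos = 1L, strand = "+",
                                coverage = 5L, meth_prob = 0.99))
  expect_error(genome_background(none), "no evaluable")
})

test_that("family methylation pools sites over copies with the >30-site QC", {
  ## 100 evaluable sites in famA copies, 40 methylated, background 0.08
  calls <- call_sites(data.table(
    contig = "c1", pos = 0:99, strand = "+", coverage = 30L,
    meth_prob = c(rep(0.95, 40), rep(0.1, 60))))
  copies <- data.table(family_id = "famA", species = "sp", contig = "c1",
                       start = 0L, end = 100L)
  fm <- family_methylation(calls, copies, background = 0.08)
  expect_equal(fm$n_sites, 100L)
  expect_equal(fm$pct_methylated, 0.40)
  expect_equal(fm$normalized_level, 5.0)
  expect_true(fm$qc_pass)
  ## exactly 30 evaluable sites -> QC fail (strict "over 30")
  fm30 <- family_methylation(calls[1:30], copies, background = 0.08)
  expect_false(fm30$qc_pass)
  expect_true(is.na(fm30$normalized_level))
  ## no overlapping sites -> missing, not an error
  far <- data.table(family_id = "famB", species = "sp", contig = "c9",
                    start = 0L, end = 100L)
  fmB <- family_methylation(calls, far, background = 0.08)
  expect_false(fmB$qc_pass)
  expect_true(is.na(fmB$pct_methylated))
  expect_error(family_methylation(calls, copies, background = 0),
               "degenerate")
})

test_that("a site under two same-family copies counts once, under two families once each", {
  calls <- call_sites(data.table(contig = "c1", pos = c(5L, 50L),
                                 strand = "+", coverage = 30L,
                                 meth_prob = 0.95))
  copies <- data.table(
    family_id = c("famA", "famA", "famB"),
    species = "sp", contig = "c1",
    start = c(0L, 0L, 0L), end = c(100L, 60L, 10L))
  fm <- family_methylation(calls, copies, background = 0.08, min_sites = 0L)
  expect_equal(fm[family_id == "famA", n_sites], 2L)  # not 4
  expect_equal(fm[family_id == "famB", n_sites], 1L)  # pos 5 only
})

test_that("normalized level is exactly 1 at background and superfamily is the member median", {
  fm <- data.table(family_id = c("a", "b", "c", "d"),
                   n_sites = c(100L, 100L, 100L, 10L),
                   n_methylated = c(10L, 40L, 20L, 5L),
                   pct_methylated = c(0.1, 0.4, 0.2, 0.5),
                   normalized_level = c(0.1, 0.4, 0.2, 0.5) / 0.2,
                   qc_pass = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fm$normalized_level[3], 1)  # pct == background of 0.2
  cls <- data.table(family_id = c("a", "b", "c", "d"),
                    class_superfamily = c("X", "X", "X", "Y"))
  sf <- superfamily_methylation(fm, cls)
  expect_equal(sf[class_superfamily == "X", pct_methylated], 0.2)
  expect_equal(sf[class_superfamily == "X", n_families], 3L)
  ## superfamily with no QC-passing member is reported missing
  expect_true(is.na(sf[class_superfamily == "Y", pct_methylated]))
  ## single member is its own median
  sf1 <- superfamily_methylation(fm[1], cls[1])
  expect_equal(sf1$pct_methylated, 0.1)
})

test_that("family percentage estimates are unbiased for the generating fractions", {
  ## simulated sites at known per-family fractions, through the call filter
  set.seed(77)
  true_frac <- c(0.05, 0.2, 0.5, 0.8)
  n_sites <- 400L
  errs <- vapply(seq_along(true_frac), function(i) {
    rec <- data.table(
      contig = "c1", pos = seq_len(n_sites) + (i - 1L) * 10000L,
      strand = "+",
      coverage = sample(5:60, n_sites, replace = TRUE),
      meth_prob = ifelse(runif(n_sites) < true_frac[i],
                         runif(n_sites, 0.801, 1), runif(n_sites, 0, 0.8)))
    copies <- data.table(family_id = "f", species = "sp", contig = "c1",
                         start = (i - 1L) * 10000L,
                         end = (i - 1L) * 10000L + n_sites + 1L)
    fm <- family_methylation(call_sites(rec), copies, background = 0.08)
    fm$pct_methylated - true_frac[i]
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.08)  # binomial noise at ~290 evaluable sites
})
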