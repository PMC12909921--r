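## Shared fixture builders (everything generated in code).

library(data.table)

## a small repeat-hit table, internally 0-based half-open
fixture_hits <- function() {
  data.table(
    query_contig = c("ctg1", "ctg1", "ctg2"),
    query_start = c(100L, 900L, 50L),
    query_end = c(500L, 1400L, 300L),
    strand = c("+", "+", "-"),
    family_id = c("famA", "famA", "famB"),
    class_superfamily = c("LINE/BovB", "LINE/BovB", "DNA/hAT-Ac"),
    consensus_start = c(0L, 380L, 10L),
    consensus_end = c(400L, 880L, 260L),
    score = c(1200, 1500, 800),
    divergence_pct = c(5.2, 6.1, 12.0),
    deletion_pct = c(0.5, 1.0, 0.0),
    insertion_pct = c(0.2, 0.0, 0.3),
    hit_id = 1:3)
}

fixture_cpg <- function() {
  data.table(contig = "chr1", pos = c(100L, 150L, 200L),
             strand = c("+", "-", "+"),
             coverage = c(25L, 12L, 48L),
             meth_prob = c(0.93, 0.10, 0.55))
}

fixture_svs <- function() {
  data.table(
    sv_id = c("sv1", "sv2", "sv3"),
    contig = c("ctg1", "ctg1", "ctg2"),
    position = c(1000L, 1040L, 5000L),
    sv_type = "INS",
    length = c(120L, 450L, 300L),
    sequence = c(strrep("ACGT", 30), strrep("AC", 225), strrep("TG", 150)),
    carriers = c("s1,s2", "s2,s3", "s4"))
}

## three-species toy tree + chain
toy_stree <- function() {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  species_tree(tree, list(
    focal = "A",
    steps = list(list(name = "A", species = "A"),
                 list(name = "AB", species = c("A", "B")),
                 list(name = "ABC", species = c("A", "B", "C")))))
}

## a tiny but complete cohort for pipeline-level tests
small_cohort_config <- function(seed = 42L, ...) {
  defaults <- list(family_birth_rate = 60 / 180, background_cpg = 20000L,
                   base_activity = 30, seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

## deterministic mutated copy of a sequence at a given identity
mutate_at_identity <- function(seq, identity, seed = 1L) {
  set.seed(seed)
  n <- nchar(seq)
  k <- round((1 - identity) * n)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(ch, collapse = "")
}
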