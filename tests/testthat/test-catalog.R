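## Catalog construction: size bins, identity clustering, representatives,
## fragment linking, abundance filtering.

test_that("size bins are half-open below with boundaries assigned upward", {
  fams <- data.table(family_id = c("a", "b", "c", "d"),
                     length = c(400L, 600L, 500L, 20000L))
  bins <- bin_by_size(fams)
  expect_equal(bins[["[1,500)"]], "a")
  expect_setequal(bins[["[500,1000)"]], c("b", "c"))
  expect_equal(bins[["[20000,Inf)"]], "d")
  expect_equal(bin_by_size(fams[0]), list())
  ## every family in exactly one bin, over random lengths
  set.seed(7)
  fams2 <- data.table(family_id = sprintf("f%03d", 1:200),
                      length = sample(c(1:30, 490:510, 999:1001, 50000), 200,
                                      replace = TRUE))
  bins2 <- bin_by_size(fams2)
  expect_setequal(unlist(bins2), fams2$family_id)
  expect_equal(sum(lengths(bins2)), 200L)
})

test_that("clustering joins >=90% pairs, splits 85% pairs, and is single-linkage", {
  set.seed(3)
  base <- random_dna(600)
  fams <- data.table(
    family_id = c("f1", "f2", "f3"),
    sequence = c(base, base, mutate_at_identity(base, 0.85, seed = 5)),
    length = 600L, class_superfamily = "Unclassified",
    source_species = "sp1")
  cl <- cluster_families(fams)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]], c("f1", "f2"))
  ## transitive closure: A~B 92%, B~C 91%, A~C ~85% -> one cluster
  A <- random_dna(800)
  B <- mutate_at_identity(A, 0.92, seed = 11)
  C <- mutate_at_identity(B, 0.91, seed = 12)
  fams3 <- data.table(family_id = c("A", "B", "C"),
                      sequence = c(A, B, C), length = 800L,
                      class_superfamily = "Unclassified",
                      source_species = "sp1")
  ## brute-force oracle: pairwise identity matrix + transitive closure
  idm <- outer(1:3, 1:3, Vectorize(function(i, j)
    seq_identity(fams3$sequence[i], fams3$sequence[j])))
  adj <- idm >= 0.90
  reach <- adj | t(adj)
  for (k in 1:3) reach <- reach | (reach[, k] %o% reach[k, ])
  expect_true(reach[1, 3])   # linked through B
  expect_lt(idm[1, 3], 0.90) # though directly below the cut
  cl3 <- cluster_families(fams3)
  expect_length(cl3, 1L)
  expect_setequal(cl3[[1]], c("A", "B", "C"))
  expect_error(cluster_families(fams3, identity_threshold = 1.2), "0, 1")
})

test_that("clustering is invariant to input order", {
  set.seed(9)
  seqs <- replicate(6, random_dna(700))
  seqs[2] <- mutate_at_identity(seqs[1], 0.95, seed = 21)
  seqs[4] <- mutate_at_identity(seqs[3], 0.93, seed = 22)
  fams <- data.table(family_id = sprintf("f%d", 1:6), sequence = seqs,
                     length = 700L, class_superfamily = "Unclassified",
                     source_species = "sp1")
  ref <- cluster_families(fams)
  for (i in 1:20) {
    shuffled <- fams[sample(.N)]
    expect_identical(cluster_families(shuffled), ref)
  }
})

test_that("representatives are the longest member, ties to smallest id", {
  members <- data.table(
    family_id = c("x", "y", "z"),
    sequence = c(strrep("A", 900), strrep("A", 950), strrep("A", 910)),
    length = c(900L, 950L, 910L),
    class_superfamily = c("LINE/BovB", "Unclassified", "LINE/BovB"),
    source_species = c("sp1", "sp2", "sp1"))
  rep <- pick_representative(members)
  expect_equal(rep$family_id, "y")
  expect_gte(rep$length, max(members$length))
  expect_equal(rep$class_superfamily, "LINE/BovB")  # adopted from members
  expect_equal(rep$source_species, "sp1,sp2")
  expect_equal(pick_representative(members[1])$family_id, "x")
  tie <- members[1:2][, length := 900L]
  expect_equal(pick_representative(tie)$family_id, "x")
  expect_error(pick_representative(members[0]), "empty")
})

test_that("fragment linking merges collinear nearby hits and nothing else", {
  two <- function(strand2 = "+", gap = 50L, cstart2 = 380L) {
    data.table(query_contig = "ctg1",
               query_start = c(100L, 500L + gap),
               query_end = c(500L, 1020L + gap),
               strand = c("+", strand2), family_id = "famA",
               class_superfamily = "LINE/X",
               consensus_start = c(0L, cstart2),
               consensus_end = c(400L, cstart2 + 520L),
               score = c(1, 1), divergence_pct = c(1, 1),
               deletion_pct = 0, insertion_pct = 0, hit_id = 1:2)
  }
  ## same family/strand, 50 bp gap, consensus 1-400 then 381-900 -> one copy
  copies <- link_fragments(two())
  expect_equal(nrow(copies), 1L)
  expect_equal(copies$n_hits, 2L)
  expect_equal(copies$total_aligned_bp, 400L + 520L)
  ## opposite strands -> two copies
  expect_equal(nrow(link_fragments(two(strand2 = "-"))), 2L)
  ## 50 kb gap -> two copies
  expect_equal(nrow(link_fragments(two(gap = 50000L))), 2L)
  ## non-collinear consensus (restarts at 0) -> two copies
  expect_equal(nrow(link_fragments(two(cstart2 = 100L))), 2L)
  ## unsorted input -> error
  expect_error(link_fragments(two()[2:1]), "sorted")
})

test_that("fragment linking equals the brute-force chaining oracle", {
  ## oracle: among all cuts of the sorted hits into consecutive blocks, the
  ## valid partition with fewest blocks (merge condition is adjacent-wise,
  ## so the coarsest valid partition is unique and equals greedy chaining)
  oracle_copies <- function(hits, max_gap = 5000L, tol = 50L) {
    n <- nrow(hits)
    ok_pair <- function(i, j) {
      hits$family_id[i] == hits$family_id[j] &&
        hits$strand[i] == hits$strand[j] &&
        hits$query_start[j] - hits$query_end[i] <= max_gap &&
        if (hits$strand[i] == "+")
          hits$consensus_start[j] >= hits$consensus_end[i] - tol
        else hits$consensus_end[j] <= hits$consensus_start[i] + tol
    }
    best <- n + 1L
    for (mask in 0:(2^(n - 1) - 1)) {
      cuts <- as.logical(bitwAnd(mask, 2^(0:(n - 2))))
      blocks <- cumsum(c(0L, cuts))
      valid <- TRUE
      for (i in seq_len(n - 1L))
        if (blocks[i] == blocks[i + 1L] && !ok_pair(i, i + 1L))
          valid <- FALSE
      if (valid) best <- min(best, max(blocks) + 1L)
    }
    best
  }
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(2:7, 1)
    start <- cumsum(sample(c(100L, 3000L, 7000L), n, replace = TRUE))
    width <- sample(100:400, n, replace = TRUE)
    cstart <- cumsum(sample(c(-30L, 200L, 500L), n, replace = TRUE)) + 600L
    hits <- data.table(query_contig = "c", query_start = start,
                       query_end = start + width,
                       strand = sample(c("+", "+", "-"), 1),
                       family_id = "f", class_superfamily = "x",
                       consensus_start = cstart,
                       consensus_end = cstart + width,
                       score = 1, divergence_pct = 1, deletion_pct = 0,
                       insertion_pct = 0, hit_id = seq_len(n))
    if (hits$strand[1] == "-")
      hits[, `:=`(consensus_start = rev(consensus_start),
                  consensus_end = rev(consensus_end))]
    got <- nrow(link_fragments(hits))
    expect_equal(got, oracle_copies(hits), info = paste("rep", rep))
  }
})

test_that("low-copy families are dropped at copy number 3 and kept at 4", {
  ab <- data.table(species = "sp1", family_id = c("a", "b", "c"),
                   copy_number = c(3L, 4L, 10L),
                   total_copy_bp = c(900, 4000, 12000))
  kept <- filter_low_copy(ab)
  expect_setequal(kept$family_id, c("b", "c"))
  expect_equal(nrow(filter_low_copy(ab[0])), 0L)
})

test_that("abundance conserves masked bp and superfamily sums equal family sums", {
  hits <- fixture_hits()
  copies <- link_fragments(hits, species = "sp1")
  ab <- abundance_table(copies)
  expect_equal(sum(ab$total_copy_bp),
               sum(hits$query_end - hits$query_start))
  cls <- data.table(family_id = c("famA", "famB"),
                    class_superfamily = c("LINE/BovB", "DNA/hAT-Ac"))
  sab <- superfamily_abundance(ab, cls)
  expect_equal(sum(sab$copy_number), sum(ab$copy_number))
})
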