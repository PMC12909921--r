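## Representative SV selection, TE annotation, region assignment,
## activity metrics, per-region insertion rates.

test_that("co-located SVs collapse to the longest record with unioned carriers", {
  svs <- fixture_svs()  # sv1/sv2 within 40 bp, sv3 elsewhere
  rep <- pick_representative_sv(svs)
  expect_equal(nrow(rep), 2L)
  locus1 <- rep[contig == "ctg1"]
  expect_equal(locus1$sv_id, "sv2")      # lengths 120 vs 450
  expect_setequal(strsplit(locus1$carriers, ",")[[1]], c("s1", "s2", "s3"))
  expect_equal(locus1$n_merged, 2L)
  ## singleton is itself
  expect_equal(pick_representative_sv(svs[3])$sv_id, "sv3")
  ## tie in length -> smallest sv_id
  tie <- copy(svs[1:2])[, length := 200L]
  expect_equal(pick_representative_sv(tie)$sv_id, "sv1")
  expect_error(pick_representative_sv(svs[0]), "empty")
})

test_that("SV TE annotation finds exact substrings and best hits, rejects noise", {
  set.seed(55)
  catalog <- data.table(
    family_id = c("famA", "famB"),
    sequence = c(random_dna(1000), random_dna(900)),
    length = c(1000L, 900L),
    class_superfamily = c("LINE/BovB", "DNA/hAT-Ac"),
    source_species = "sp")
  ## exact 300-bp substring of famA
  sub <- substring(catalog$sequence[1], 201, 500)
  hit <- annotate_sv_te(sub, catalog)
  expect_equal(hit$family_id, "famA")
  expect_equal(hit$identity, 1)
  ## best hit between two candidates at 95% vs 80% identity
  cat2 <- data.table(
    family_id = c("near", "far"),
    sequence = c(mutate_at_identity(sub, 0.95, seed = 2),
                 mutate_at_identity(sub, 0.80, seed = 3)),
    length = 300L, class_superfamily = "X", source_species = "sp")
  hit2 <- annotate_sv_te(sub, cat2)
  expect_equal(hit2$family_id, "near")
  ## random sequences never associate (false-hit rate over 40 draws)
  fp <- sum(vapply(1:40, function(i)
    !is.na(annotate_sv_te(random_dna(400), catalog)$family_id),
    logical(1)))
  expect_lt(fp / 40, 0.05)
  ## empty sequence -> warning, no hit
  expect_warning(none <- annotate_sv_te("", catalog), "empty")
  expect_true(is.na(none$family_id))
})

test_that("annotation is sensitive up to 15% divergence and batch equals single", {
  set.seed(66)
  catalog <- data.table(family_id = sprintf("fam%02d", 1:5),
                        sequence = replicate(5, random_dna(1200)),
                        length = 1200L, class_superfamily = "X",
                        source_species = "sp")
  draws <- lapply(1:30, function(i) {
    f <- sample(5, 1)
    w0 <- sample(1:600, 1)
    len <- sample(300:600, 1)
    div <- runif(1, 0, 0.15)
    list(f = f, seq = mutate_at_identity(
      substring(catalog$sequence[f], w0, w0 + len - 1L), 1 - div,
      seed = 100 + i))
  })
  svs <- data.table(sv_id = sprintf("s%02d", 1:30), contig = "c",
                    position = (1:30) * 1000L, sv_type = "INS",
                    length = vapply(draws, function(d) nchar(d$seq),
                                    integer(1)),
                    sequence = vapply(draws, `[[`, character(1), "seq"),
                    carriers = "x1")
  ann <- annotate_svs(svs, catalog)
  truth <- catalog$family_id[vapply(draws, `[[`, integer(1), "f")]
  expect_gte(mean(ann$te_family == truth, na.rm = TRUE), 0.95)
  expect_lte(mean(is.na(ann$te_family)), 0.05)
  ## batch agrees with the single-SV operation
  singles <- vapply(seq_len(nrow(svs)), function(i)
    annotate_sv_te(svs$sequence[i], catalog)$family_id, character(1))
  expect_equal(ann$te_family, singles)
})

test_that("region assignment applies exon > intron > intergenic precedence", {
  genes <- data.table(gene_id = c("gA", "gA", "gB"),
                      contig = "c1", strand = "+",
                      exon_start = c(100L, 300L, 250L),
                      exon_end = c(200L, 400L, 260L))
  ## gB's exon sits inside gA's intron: precedence says exon
  expect_equal(assign_region(c(150L, 220L, 500L, 255L), "c1", genes),
               c("exon", "intron", "intergenic", "exon"))
  ## empty gene set -> everything intergenic
  expect_equal(assign_region(10L, "c1", genes[0]), "intergenic")
})

test_that("family activity metrics follow their definitions", {
  ann <- data.table(
    sv_id = sprintf("s%02d", 1:24),
    sv_type = "INS",
    te_family = c(rep("famA", 12), rep("famB", 4), rep("famC", 3),
                  rep(NA_character_, 5)),
    region = c(rep("exon", 2), rep("intron", 10), rep("intergenic", 4),
               rep("intron", 3), rep("exon", 5)),
    carriers = "x1")
  ab <- data.table(species = "sp", family_id = c("famA", "famB"),
                   copy_number = c(48L, 8L), total_copy_bp = c(1, 1))
  expect_message(act <- family_activity(ann, ab), "excluded")
  a <- act[family_id == "famA"]
  expect_equal(a$spreading_efficiency, 12 / 48)
  expect_equal(a$exonic_ratio, 2 / 12)
  expect_true(a$highly_active)                     # 12 > 3
  expect_true(act[family_id == "famB", highly_active])   # 4 > 3
  expect_false(act[family_id == "famC", highly_active])  # 3 is not > 3
  ## family without reference abundance: excluded from efficiency, kept
  expect_true(is.na(act[family_id == "famC", spreading_efficiency]))
  ## scale invariance
  ab2 <- copy(ab)[family_id == "famA", copy_number := 96L]
  ann2 <- rbind(ann, ann[te_family == "famA"][, sv_id := paste0(sv_id, "b")])
  act2 <- suppressMessages(family_activity(ann2, ab2))
  expect_equal(act2[family_id == "famA", spreading_efficiency], 12 / 48)
  ## exonic ratio: 2 exonic of 20 insertions
  ann3 <- data.table(sv_id = as.character(1:20), sv_type = "INS",
                     te_family = "f", carriers = "x",
                     region = c(rep("exon", 2), rep("intron", 18)))
  act3 <- suppressMessages(family_activity(
    ann3, data.table(species = "sp", family_id = "f", copy_number = 10L,
                     total_copy_bp = 1)))
  expect_equal(act3$exonic_ratio, 0.10)
})

test_that("length-normalised region rates reproduce a constructed 2.8x deficit", {
  ## genes giving 1e6 exonic and 1e6 intronic bp
  genes <- data.table(gene_id = rep(sprintf("g%03d", 1:100), each = 2),
                      contig = "c1", strand = "+",
                      exon_start = rep((0:99) * 40000L, each = 2) +
                        c(0L, 15000L),
                      exon_end = rep((0:99) * 40000L, each = 2) +
                        c(5000L, 20000L))
  ## each gene: two 5 kb exons, one 10 kb intron => 1e6 exon, 1e6 intron
  regions <- c(rep("exon", 10), rep("intron", 28), rep("intergenic", 5))
  rr <- lengthnorm_region_rates(regions, genes, genome_length = 8e6)
  expect_equal(rr$intron_exon_ratio, 2.8)
  expect_equal(rr$rates[region == "exon", bp], 1e6)
  expect_equal(sum(rr$rates$count), length(regions))
  ## equal counts, equal lengths -> ratio 1, chi-square ~ 0
  rr2 <- lengthnorm_region_rates(c(rep("exon", 10), rep("intron", 10)),
                                 genes, genome_length = 8e6)
  expect_equal(rr2$intron_exon_ratio, 1)
  expect_lt(rr2$chisq, 1e-8)
  ## zero exonic SVs: infinite ratio with a Haldane-corrected alternative
  rr3 <- lengthnorm_region_rates(rep("intron", 10), genes,
                                 genome_length = 8e6)
  expect_true(is.infinite(rr3$intron_exon_ratio))
  expect_equal(rr3$intron_exon_ratio_haldane, 10.5 / 0.5)
  expect_error(lengthnorm_region_rates("exon", genes[0], 1e6), "zero")
})
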