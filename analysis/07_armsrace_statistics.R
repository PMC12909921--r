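#!/usr/bin/env Rscript
## Step 7 — the arms-race statistical battery on the assembled family table:
## correlations, ANCOVA models, group tests, ordination, dendrogram
## congruence, and the desk-scale worked examples from published counts.

suppressMessages({library(armsraceTE); library(data.table)})

dir <- "results/cohort"
stree <- read_species_tree(file.path(dir, "tree.nwk"),
                           file.path(dir, "clades.yaml"))
focal <- stree$focal
report <- list()

abundance <- fread("results/tables/abundance.tsv")
ages <- fread("results/tables/ages.tsv")
meth <- fread("results/tables/family_methylation.tsv")
act <- fread("results/tables/family_activity.tsv")
catalog <- read_consensus_fasta("results/tables/catalog.fa")

fam <- Reduce(function(a, b) merge(a, b, by = "family_id", all.x = TRUE),
              list(abundance[species == focal,
                             .(family_id, copy_number)],
                   ages, meth[, .(family_id, pct_methylated,
                                  normalized_level, qc_pass)],
                   act[, .(family_id, sv_count, spreading_efficiency,
                           highly_active, exonic_ratio)]))
fam[is.na(sv_count), sv_count := 0L]
fam[is.na(highly_active), highly_active := FALSE]
fam[is.na(spreading_efficiency) & copy_number > 0,
    spreading_efficiency := sv_count / copy_number]
d <- fam[qc_pass == TRUE & age_group != "unknown"]

## abundance ~ methylation, and spreading efficiency ~ methylation
r_ab <- correlation(d$pct_methylated, transform_abundance(d$copy_number))
r_se <- correlation(d$pct_methylated, d$spreading_efficiency)
cat(sprintf("Spearman meth vs log-abundance: rho = %.2f (p = %.2g, n = %d)\n",
            r_ab$rho, r_ab$p, r_ab$n))
cat(sprintf("Spearman meth vs spreading efficiency: rho = %.2f (p = %.2g, n = %d)\n",
            r_se$rho, r_se$p, r_se$n))
report$spearman_meth_abundance <- r_ab
report$spearman_meth_spreading <- r_se

## ANCOVA: log10(abundance + 1) ~ methylation x age;
##         log10(spreading + 1) ~ methylation x age
a1 <- fit_ancova(transform_abundance(d$copy_number), d$pct_methylated,
                 d$age_group)
a2 <- fit_ancova(transform_abundance(d$spreading_efficiency),
                 d$pct_methylated, d$age_group)
cat(sprintf("ANCOVA abundance: F(1, %d)_meth = %.1f (p = %.2g)\n",
            a1$residual_df, a1$table$f[1], a1$table$p[1]))
cat(sprintf("ANCOVA spreading: F(1, %d)_meth = %.1f (p = %.2g)\n",
            a2$residual_df, a2$table$f[1], a2$table$p[1]))
report$ancova_abundance <- a1[c("table", "residual_df", "n")]
report$ancova_spreading <- a2[c("table", "residual_df", "n")]

## per-age-group methylation/spreading correlation (the arms-race gradient)
grad <- d[!is.na(rank), {
  ct <- correlation(pct_methylated, spreading_efficiency)
  .(rho = ct$rho, p = ct$p, n = ct$n)
}, keyby = .(rank, age_group)]
grad[, p_bh := p.adjust(p, method = "BH")]  # optional FDR control
print(grad)
report$per_age_correlation <- grad

## highly-active share in youngest vs oldest group (Fisher, sample OR)
young <- d[rank == 0]; old <- d[rank == max(rank, na.rm = TRUE)]
tab <- matrix(c(sum(young$highly_active), sum(old$highly_active),
                sum(!young$highly_active), sum(!old$highly_active)), 2)
ft <- group_tests(tab)
cat(sprintf("highly active: young %d/%d vs ancient %d/%d, OR = %.2f (p = %.3f)\n",
            tab[1, 1], nrow(young), tab[2, 1], nrow(old),
            ft$odds_ratio, ft$p))
report$fisher_highly_active <- ft

## Wilcoxon: normalized methylation of young families vs 1 (background)
w <- group_tests(young$normalized_level, old$normalized_level)
report$wilcoxon_young_vs_old_meth <- w

## superfamily-level ordination and dendrogram congruence across genomes
species <- setdiff(stree$chain[[length(stree$chain)]]$species,
                   stree$excluded)
copies <- fread("results/tables/copies.tsv")
ab_all <- abundance_table(copies)
sab <- superfamily_abundance(ab_all, catalog[, .(family_id,
                                                 class_superfamily)])
A <- dcast(sab, species ~ class_superfamily, value.var = "copy_number",
           fill = 0)
Am <- as.matrix(A, rownames = "species")
ord <- ordination(Am, mode = "abundance")
cat(sprintf("abundance PCA: PC1 %.0f%%, PC2 %.0f%% of variance\n",
            100 * ord$explained[1], 100 * ord$explained[2]))
report$pca_explained <- ord$explained

## methylation matrix per genome (superfamily medians), then congruence
sf_list <- lapply(species, function(sp) {
  calls <- call_sites(read_cpg_table(file.path(dir, paste0(sp, "_cpg.tsv"))))
  bg <- genome_background(calls)
  fm <- family_methylation(calls, copies[species == sp], bg)
  sf <- superfamily_methylation(fm, catalog[, .(family_id,
                                                class_superfamily)])
  sf[, species := sp]
  sf
})
sf_all <- rbindlist(sf_list)
M <- dcast(sf_all, species ~ class_superfamily,
           value.var = "normalized_level")
Mm <- as.matrix(M, rownames = "species")
keep <- colSums(is.na(Mm)) == 0
Mm <- Mm[, keep, drop = FALSE]
common <- intersect(colnames(Am), colnames(Mm))  # drops Unclassified
Mm <- Mm[, common, drop = FALSE]
Am2 <- transform_abundance(Am[rownames(Mm), common, drop = FALSE])
cg <- dendrogram_congruence(Am2, standardize_rows(Mm),
                            n_permutation = 1000, seed = 1)
cat(sprintf("dendrogram congruence (abundance vs methylation): r_coph = %.2f, p = %.3f\n",
            cg$statistic, cg$p))
report$dendrogram_congruence <- cg

## desk-scale worked examples from the published counts
report$published_fisher <- group_tests(matrix(c(71, 493, 32, 352), 2))
report$published_enrichment_defence <- enrichment_binomial(15, 49, 0.07)
report$published_enrichment_pirna <- enrichment_binomial(10, 31, 0.07)
cat(sprintf("published 2x2: sample OR = %.2f; defence-gene enrichment p = %.2g\n",
            report$published_fisher$odds_ratio,
            report$published_enrichment_defence$p))

fwrite(fam, "results/tables/family_table.tsv", sep = "\t")
jsonlite::write_json(report, "results/armsrace_report.json",
                     auto_unbox = TRUE, digits = 6, force = TRUE)
cat("report written to results/armsrace_report.json\n")
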