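#!/usr/bin/env Rscript
## Step 4 — CpG-aware Kimura distances and divergence-landscape classes
## for the focal species.

suppressMessages({library(armsraceTE); library(data.table)})

dir <- "results/cohort"
stree <- read_species_tree(file.path(dir, "tree.nwk"),
                           file.path(dir, "clades.yaml"))
aln <- fread(file.path(dir, paste0(stree$focal, "_alignments.tsv")))
kd <- copy_kd(aln)
prof <- kd_profiles(kd)
cat(sprintf("KD computed for %d copies in %d families (%d saturated)\n",
            nrow(kd), uniqueN(kd$family_id), sum(!is.finite(kd$kd))))
print(prof[, .N, by = shape_class])

truth <- fread(file.path(dir, "truth", "families.tsv"))
m <- merge(kd[, .(median_kd = median(kd, na.rm = TRUE)), by = family_id],
           truth[, .(family_id, true_rank)], by = "family_id")
m <- m[!is.na(true_rank)]
ct <- correlation(m$true_rank, m$median_kd)
cat(sprintf("median family KD vs true age rank: Spearman rho = %.2f (p = %.2g)\n",
            ct$rho, ct$p))

## per (family, bin) histogram table
hist_dt <- kd[is.finite(kd), .(count = .N),
              by = .(family_id, bin = pmin(floor(kd), 49))]
fwrite(kd, "results/tables/kd_copies.tsv", sep = "\t")
fwrite(hist_dt, "results/tables/kd_histograms.tsv", sep = "\t")
fwrite(prof, "results/tables/kd_profiles.tsv", sep = "\t")
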