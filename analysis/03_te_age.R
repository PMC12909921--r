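#!/usr/bin/env Rscript
## Step 3 — effective copy numbers, presence calls, TE age groups.

suppressMessages({library(armsraceTE); library(data.table)})

dir <- "results/cohort"
stree <- read_species_tree(file.path(dir, "tree.nwk"),
                           file.path(dir, "clades.yaml"))
catalog <- read_consensus_fasta("results/tables/catalog.fa")
abundance <- fread("results/tables/abundance.tsv")

presence <- presence_matrix(abundance, catalog[, .(family_id, length)],
                            stree)
ages <- assign_ages(presence, stree)
s <- age_summary(ages, stree)
print(s)

truth <- fread(file.path(dir, "truth", "families.tsv"))
m <- merge(ages, truth[, .(family_id, true_age_group)], by = "family_id")
cat(sprintf("age-group accuracy vs ground truth: %.1f%% (n = %d)\n",
            100 * mean(m$age_group == m$true_age_group), nrow(m)))

fwrite(presence, "results/tables/presence.tsv", sep = "\t")
fwrite(ages, "results/tables/ages.tsv", sep = "\t")
fwrite(s, "results/tables/age_summary.tsv", sep = "\t")
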