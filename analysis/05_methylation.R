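#!/usr/bin/env Rscript
## Step 5 — methylation calling, genome background, family and superfamily
## methylation for the focal species.

suppressMessages({library(armsraceTE); library(data.table)})

dir <- "results/cohort"
stree <- read_species_tree(file.path(dir, "tree.nwk"),
                           file.path(dir, "clades.yaml"))
focal <- stree$focal

calls <- call_sites(read_cpg_table(file.path(dir, paste0(focal, "_cpg.tsv"))))
print(calls[, .N, by = status])
bg <- genome_background(calls)
cat(sprintf("genome background methylation: %.3f\n", bg))

copies <- fread("results/tables/copies.tsv")[species == focal]
catalog <- read_consensus_fasta("results/tables/catalog.fa")
fam <- family_methylation(calls, copies, bg)
cat(sprintf("%d families, %d pass the >30-CpG QC\n",
            nrow(fam), sum(fam$qc_pass)))
sf <- superfamily_methylation(fam, catalog[, .(family_id, class_superfamily)])

truth <- fread(file.path(dir, "truth", "families.tsv"))
m <- merge(fam[qc_pass == TRUE], truth[, .(family_id, meth_fraction)],
           by = "family_id")
cat(sprintf("mean |estimate - truth| over QC families: %.3f\n",
            m[, mean(abs(pct_methylated - meth_fraction))]))

fwrite(fam, "results/tables/family_methylation.tsv", sep = "\t")
fwrite(sf, "results/tables/superfamily_methylation.tsv", sep = "\t")
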