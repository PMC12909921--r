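#!/usr/bin/env Rscript
## Step 2 — non-redundant family catalog, fragment linking, abundance.
##
## Per-species consensus libraries are size-binned, clustered at >= 90%
## identity and represented by their longest member; RepeatMasker-style
## fragments are linked into copies; families with <= 3 copies are dropped.

suppressMessages({library(armsraceTE); library(data.table)})

dir <- "results/cohort"
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

stree <- read_species_tree(file.path(dir, "tree.nwk"),
                           file.path(dir, "clades.yaml"))
species <- setdiff(stree$chain[[length(stree$chain)]]$species,
                   stree$excluded)

libs <- rbindlist(lapply(species, function(sp)
  read_consensus_fasta(file.path(dir, paste0(sp, "_consensi.fa")), sp)))
libs[, family_id := paste0(family_id, "@", source_species)]
built <- build_catalog(libs)
catalog <- built$catalog
catalog[, family_id := sub("@.*$", "", family_id)]
catalog <- catalog[!duplicated(family_id)]
cat(sprintf("catalog: %d redundant entries -> %d representative families\n",
            nrow(libs), nrow(catalog)))

copies <- rbindlist(lapply(species, function(sp)
  link_fragments(read_repeat_hits(file.path(dir, paste0(sp, ".out")),
                                  "rm_out"), species = sp)))
ab <- abundance_table(copies)
abf <- filter_low_copy(ab)
cat(sprintf("linked %d copies; %d (species, family) pairs, %d after the >3-copy filter\n",
            nrow(copies), nrow(ab), nrow(abf)))

write_consensus_fasta(catalog, "results/tables/catalog.fa")
fwrite(built$clusters, "results/tables/clusters.tsv", sep = "\t")
fwrite(copies, "results/tables/copies.tsv", sep = "\t")
fwrite(abf, "results/tables/abundance.tsv", sep = "\t")
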