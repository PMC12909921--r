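#!/usr/bin/env Rscript
## Step 1 — generate the reference synthetic cohort.
##
## Seven termite species plus outgroups, a nominal 200 TE families born
## along the focal (M. bellicosus) lineage, methylation-dependent
## suppression of mobilisation, erosion and divergence with age, and
## population SVs biased away from exons. All downstream steps read the
## files written here; ground truth goes to results/cohort/truth/.

suppressMessages(library(armsraceTE))

seed <- 1L
out_dir <- "results/cohort"

cfg <- cohort_config(seed = seed)
coh <- simulate_cohort(cfg)
write_cohort(coh, out_dir)

cat(sprintf("cohort written to %s\n", out_dir))
cat(sprintf("  families: %d (%s)\n", nrow(coh$families),
            paste(sprintf("%s=%d",
                          names(table(coh$families$true_age_group)),
                          table(coh$families$true_age_group)),
                  collapse = ", ")))
cat(sprintf("  copies: %d over %d species; SVs: %d; CpG records: %d\n",
            nrow(coh$copies), length(unique(coh$copies$species)),
            nrow(coh$svs), nrow(coh$cpg)))
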