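Package: armsraceTE
Title: Transposable-Element / DNA-Methylation Arms-Race Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying evolutionary arms races between
    transposable elements (TEs) and host DNA methylation across a species
    phylogeny. Provides readers and writers for RepeatMasker-style repeat
    annotations, per-CpG methylation tables, structural-variant records and
    species trees; builds a non-redundant multi-species TE family catalog and
    links annotation fragments into copies; assigns TE families an
    evolutionary age group from presence/absence over a nested clade chain;
    computes CpG-aware Kimura 2-parameter divergences of copies to their
    family consensus and classifies divergence landscapes; aggregates CpG
    methylation per family and superfamily with background normalisation;
    quantifies TE activity from population structural variants (spreading
    efficiency, exonic-insertion bias); and runs the statistical battery
    linking the layers (ANCOVA, Spearman correlations, Fisher and rank-sum
    tests, exact binomial enrichment, PCA, dendrogram-congruence permutation
    tests). A synthetic-cohort simulator with full ground truth emulates TE
    birth, methylation-dependent suppression, sequence divergence, length
    erosion and selection against exonic insertion, so every stage is
    exercised end-to-end without access to genome-scale data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
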