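# armsraceTE

Do hosts and their transposable elements (TEs) fight a measurable arms
race? In insects with DNA methylation, the prediction is concrete: young TE
families invade, mobilise, and hit exons; hosts methylate them; methylation
suppresses their spread; and as families age they erode into short,
diverged, barely mobile remnants whose methylation is no longer worth
maintaining. `armsraceTE` is an R package plus analysis workflow for
measuring every link in that chain across a multi-species phylogeny —
built around a termite-like study design with *Macrotermes bellicosus* as
the focal species — and validating the whole pipeline end to end on a
synthetic cohort with known ground truth.

## What the package measures

* **Family catalog** — multi-species consensus libraries reduced to a
  non-redundant catalog: size bins, single-linkage clustering at >= 90%
  identity, longest-member representatives
  (`bin_by_size()`, `cluster_families()`, `pick_representative()`).
* **Copies and abundance** — RepeatMasker-style fragments linked into
  copies (gap <= 5 kb, collinear consensus spans), abundance per family
  and superfamily, and a strict more-than-3-copies floor
  (`link_fragments()`, `abundance_table()`, `filter_low_copy()`).
* **TE age** — presence calls from effective copy number
  (ECN = copy bp / consensus length, present iff ECN > 5) and a
  Dollo-style ladder over a nested clade chain
  (focal ⊂ Macrotermitinae ⊂ Termitidae ⊂ Geoisoptera ⊂ ancient);
  phylogeny-violating patterns are flagged `unknown` (horizontal
  transfer) (`presence_matrix()`, `assign_age()`).
* **Divergence** — CpG-aware Kimura 2-parameter distance of each copy to
  its consensus, `KD = 100·(−½)ln[(1−2p−q)√(1−2q)]`, with transitions at
  consensus CpG columns down-weighted to 1/10; family KD landscapes
  classified into recent expansion / remnant / mixed
  (`count_site_patterns()`, `kimura2p()`, `classify_kd_profile()`).
* **Methylation** — site calls at coverage 10–50x and probability > 0.80,
  family pooling over copies with a > 30-CpG QC floor, background
  normalisation, superfamily medians (`call_sites()`,
  `family_methylation()`).
* **SV activity** — representative multi-sample SV calls, best-hit TE
  annotation (seed-and-extend local alignment, coverage >= 0.5 of the
  shorter sequence), breakpoint regions with exon > intron > intergenic
  precedence, spreading efficiency (SVs per existing copy), exonic
  insertion ratios, and length-normalised per-region insertion rates
  (`pick_representative_sv()`, `annotate_svs()`, `family_activity()`).
* **Statistics** — sequential-SS ANCOVA (`log10(y+1) ~ methylation × age`),
  midrank Spearman with exact small-sample p, Fisher tests reporting the
  sample odds ratio, exact binomial enrichment with Clopper–Pearson
  intervals, centred PCA, and a dendrogram-congruence permutation test on
  cophenetic correlations (`fit_ancova()`, `correlation()`,
  `group_tests()`, `enrichment_binomial()`, `ordination()`,
  `dendrogram_congruence()`).
* **Synthetic cohort** — `cohort_config()` / `simulate_cohort()` /
  `write_cohort()` generate a fully ground-truthed 6-species cohort (family
  births along the phylogeny, methylation-suppressed mobilisation, erosion
  and divergence with age, exon-avoiding insertions), and
  `inject_horizontal_transfer()` plants phylogeny violations the age
  classifier must catch.

## Worked example

The desk-scale census statistics, straight from published counts — 71 of
103 young families highly active versus 493 of 845 ancient ones, and 15 of
49 TE-defence genes under positive selection against a 7% genomic
background:

```r
library(armsraceTE)

group_tests(matrix(c(71, 493, 103 - 71, 845 - 493), nrow = 2))
#> $odds_ratio      1.584178   (sample, cross-product)
#> $odds_ratio_cmle 1.582962   (conditional MLE)
#> $p               0.04328    $conf_int 1.00 2.54

enrichment_binomial(15, 49, 0.07)
#> $proportion 0.3061  $p 7.53e-07  $conf_int 0.183 0.454
```

The young cohort is ~1.6× as likely to be highly active, and defence genes
are ~4× enriched for positive selection — both arms-race signatures. A
phylogeny-violating presence pattern is refused an age:

```r
assign_age(c("M_bellicosus", "C_secundus"), termite_species_tree())
#> $age_group "unknown"   $rank NA
```

And the divergence core on a copy with 10% transitions, 5% transversions:

```r
kimura2p(0.10, 0.05)
#> [1] 17.01812
```

## The analysis workflow

`analysis/01_simulate_cohort.R` … `analysis/07_armsrace_statistics.R` run
the whole study on the reference synthetic cohort, writing tables under
`results/`. With the default seed the run prints, among other things:
a 639-entry redundant library collapsing to 203 representative families;
age-group recovery at 100% accuracy against ground truth; median family KD
rising with true age (Spearman rho = 0.97); Spearman(methylation,
spreading efficiency) = −0.53 (p = 2.4e-14) overall, strengthening from
−0.55 in ancient to −0.81 in young families; and an intron/exon insertion
rate ratio of 2.2 (chi-square p = 5e-4) against a generating penalty of
1/0.36 ≈ 2.8.

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

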