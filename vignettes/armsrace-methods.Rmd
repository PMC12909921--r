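---
title: "Methods: transposable elements versus host DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposable elements versus host DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Transposable elements (TEs) replicate selfishly inside host genomes; hosts
defend themselves, in many insects, by CpG methylation of TE copies. If the
interaction is a genuine arms race, four signatures should be measurable
across a phylogeny: (i) young, recently invading TE families mobilise more
and insert into harmful places (exons) more often; (ii) heavily methylated
families spread less; (iii) host defence concentrates on the families that
are currently dangerous, so the methylation–spreading association is
strongest in young families; and (iv) ancient families decay — short,
diverged, poorly mobile remnants whose methylation is no longer maintained.

`armsraceTE` implements the full measurement pipeline for these signatures
— family catalog construction, phylogenetic age assignment, CpG-aware
divergence, methylation quantification, structural-variant (SV) activity
metrics, and the statistical models — together with a synthetic-cohort
generator that encodes the arms-race dynamics with known ground truth, so
every stage can be validated end to end without genome-scale data.

# Pipeline components and their conventions

## Coordinates

Everything internal is 0-based half-open. RepeatMasker `.out` tables and
GFF3 (1-based inclusive) are converted exactly once, at the parse/write
boundary; minus-strand consensus coordinates (written `(left) end begin`)
are normalised on input so `consensus_start < consensus_end` always holds.
CpG records are keyed by the cytosine position on the annotated strand and
never strand-collapsed, because upstream callers differ in whether they
report per cytosine or per dinucleotide; collapsing is lossy, keeping both
strands is not.

## Family catalog

Multi-species consensus libraries are reduced to a non-redundant catalog
by size binning (`[1,500) [500,1e3) [1e3,2e3) [2e3,5e3) [5e3,1e4) [1e4,2e4)
[2e4,Inf)`, boundary lengths assigned to the upper bin), single-linkage
clustering within bins at >= 90% identity, and retention of the longest
member (ties break to the smallest id). Identity is matches over alignment
columns — gaps count as mismatch — on a fit alignment of the shorter
sequence onto the longer; for equal-length pairs the gap-free alignment is
computed exactly, and a shared-11-mer prefilter (scaled to 5% of the
shorter sequence's k-mers, far below the ~31% survival of a 90%-identical
pair) keeps the pair list short. Single linkage mirrors the transitive
behaviour of greedy clustering tools and makes the result provably
order-invariant.

## Fragment linking

Annotation rows are fragments, not copies. Consecutive hits on one contig
merge into one copy when they share family and strand, the genomic gap is
at most 5 kb, and the consensus spans are collinear (next fragment starts
at or after the previous consensus end minus a 50 bp tolerance; mirrored on
the minus strand). The 5 kb gap and 50 bp tolerance are exposed as
arguments; both are deliberately permissive defaults for fragmented
assemblies. Families with three or fewer linked copies are discarded
before all downstream analyses.

## TE age from presence/absence

Presence in a genome is an effective copy number (ECN = total copy bp /
consensus length) strictly above 5. Age groups are read off a nested clade
chain running from the focal species outward (focal; Macrotermitinae;
Termitidae; Geoisoptera; ancient, the last reachable through either deep
in-group tip). The operational rule is a Dollo-style ladder over the chain
"rings" (species added at each step): the age group is the outermost
occupied ring, and the pattern is consistent only when every ring between
the innermost and outermost occupied rings is also occupied. Inconsistent
patterns — e.g. present in the focal species and a deep tip but nothing in
between — violate vertical descent, suggest horizontal transfer, and are
classified "unknown" and excluded from age-stratified statistics. Presence
in a ring means at least one present species in it: requiring all members
would misclassify families lost secondarily in one lineage. A committed
63-pattern truth table freezes this convention exhaustively for the 6-tip
chain; one consequence worth noting is that a pattern occupying only a deep
ring classifies to that ring's group (such families never appear in a
focal-species catalog, so the case is theoretical). Two distant outgroups
are excluded from presence calling entirely: at more than 120 My, shared
families are more plausibly re-introductions than descent.

## CpG-aware Kimura divergence

Each copy is aligned to its family consensus and the Kimura 2-parameter
distance computed as `KD = 100 * (-1/2) ln[(1 - 2p - q) sqrt(1 - 2q)]`,
with `p` and `q` the transition and transversion proportions over
evaluable columns (gaps and ambiguity codes skip the column). Transitions
at consensus CpG columns are down-weighted to `w_cpg = 1/10` of a
substitution before forming `p`: methylated CpGs deaminate so fast that
unweighted counting conflates methylation history with age. The weight is
not printed in the literature the convention descends from, so it is an
argument; `w_cpg = 1` provably recovers plain K2P. Copies outside the
model's domain (`1 - 2p - q <= 0`) are reported saturated (`NA`) and
excluded from histograms.

Family KD histograms (unit bins 0–50, values above 50 clamped into the last
bin) are smoothed with a 3-bin moving average; local maxima with
topographic prominence at least 5% of the copy count are modes. One mode
below KD 10 is a recent expansion; one mode above 20 is a remnant family;
prominent modes on both sides are a mixed history; everything else
(including families under 20 copies) is unresolved. Smoothing window,
prominence and the cuts are arguments — the mode-reading step is inherently
heuristic and is documented as such.

## Methylation quantification

A CpG site is evaluable at coverage 10–50x inclusive and methylated when
its 5mC probability strictly exceeds 0.80; "between 10 and 50" is read
inclusively and "over 80%" strictly, and all four boundaries are arguments.
Family methylation pools evaluable sites over all copies (a site under two
copies of one family counts once; under copies of two families, once per
family); families with 30 or fewer pooled sites fail QC and are dropped
from downstream statistics. Levels are normalised by the genome-wide
background (methylated / evaluable over all sites), so 1 means background.
Superfamily levels are medians over QC-passing member families, reported
missing when no member passes.

## SV activity

Multi-sample SV calls at one locus (same contig and type, breakpoints
chaining within 100 bp) are collapsed to the longest-sequence
representative with unioned carriers. TE association is a best-hit search
of the SV sequence against the catalog: an 11-mer seed finds the dominant
diagonal, an ungapped maximal-scoring segment (match 2, mismatch −3)
extends it, and a full Smith–Waterman (gap −5 per position) is the
fallback when the diagonal explains the pair poorly; the SV is
TE-associated only if aligned bases cover at least half of the shorter of
SV and consensus. Regions are assigned at the breakpoint with exon >
intron > intergenic precedence — an insertion occupies a point in the
reference, so the single breakpoint is the honest location. Family
activity metrics: SV count, spreading efficiency (SV count / reference
copy number — mobilisation success per existing copy), exonic insertion
ratio, and a `highly_active` flag at SV count strictly above 3.
Length-normalised insertion rates per region are compared with a
two-proportion test with trials = bp, with a Haldane-corrected ratio
reported when a count is zero.

## Statistics

Abundances are `log10(x + 1)`-transformed. The two ANCOVA models —
`log10(abundance + 1) ~ methylation * age` and
`log10(spreading efficiency + 1) ~ methylation * age` — are fitted by
least squares and summarised with sequential (Type I) sums of squares in
formula order, the convention that reproduces the published df shape
(n = 2144 families, 5 age levels, term dfs 1/4/4, residual df 2134). No
other SS type is offered; one reproducible convention beats a switch.
Spearman correlations use midranks, with the exact permutation p for
n <= 30 without ties and the t approximation otherwise. Fisher's exact
test reports the sample (cross-product) odds ratio alongside the
conditional-MLE estimate, because printed odds ratios in the field are
cross-products. Binomial enrichment is exact (point-probability two-sided
p, Clopper–Pearson interval). PCA is centred, unscaled, SVD-based, on
transformed abundance or within-genome-standardised methylation, with each
component's sign fixed so its largest-magnitude loading is positive.
Dendrogram congruence clusters both matrices (Euclidean distance, complete
linkage — the defaults of the heatmap tooling this mirrors), takes the
Pearson correlation of cophenetic distances as the statistic, and permutes
the leaf labels of the second dendrogram for the null;
`p = (1 + #{perm >= obs}) / (B + 1)`. The cophenetic statistic is this
package's choice; the permutation scheme makes it calibrated regardless
(checked by a 200-seed uniformity test). No multiple-testing correction is
applied by default; a Benjamini–Hochberg adjustment is a one-liner
(`p.adjust(p, "BH")`) and is demonstrated in the analysis scripts.

# The synthetic cohort

## Generative model

The generator emulates the statistical structure the analysis assumes, on
an 8-tip ultrametric termite-like phylogeny (six in-group species, splits
at 20/50/80/130/140 My; two outgroups excluded from analysis). Families
are born by a Poisson process along the branches of the focal lineage plus
the sister terminal branch, at `family_birth_rate` families per My
(default 200/180 — a nominal 200 families). Each family carries:

* a random consensus (median 1200 bp, lognormal sd 0.1 — kept narrow so
  that group-mean copy length reflects erosion rather than library
  composition);
* a superfamily label (drawn from eleven common labels plus
  "Unclassified"); labels are assigned independently of age, so
  superfamily composition carries *no* lineage signal — cross-genome
  congruence tests on this cohort behave like their null, and the
  congruence machinery is validated by calibration instead;
* a methylated-CpG fraction from a Beta whose mean falls linearly with
  birth age from 0.33 (young; about 4x a 0.08 background) to 0.077 (about
  0.96x background) and whose concentration rises from 2.5 to 20: young
  invaders are both more methylated and far more heterogeneous, ancient
  families sit uniformly near background. The means mirror the reported
  young/ancient medians of roughly 4.2x and 0.7x background; the
  concentrations are this package's choice of heterogeneity contrast.

Copies accumulate in every descendant species as a birth burst (expected
22) plus a trickle saturating at 10 more with half-life
`activity_halflife` (50 My); insertion ages follow. Copy length erodes
exponentially (expected halving every `erosion_halflife` = 100 My, with
lognormal per-copy noise, floor 80 bp), and per-copy divergence from the
consensus is `2 * mutation_rate * age` in expectation
(`mutation_rate = 8e-4`/site/My), realised by actual substitution sampling
with a 2:1 transition:transversion ratio for the focal species, whose
copy/consensus alignments are emitted. These rates place young families
near KD 1–3 and ancient ones near KD 20–25, inside the K2P domain.

Population SVs for the focal species are emitted per family at rate
`base_activity * 2^(-birth_age / activity_halflife) *
exp(-suppression_beta * methylation / background)`, with lognormal
unexplained variance (`activity_sd_log = 0.6`). `suppression_beta = 0.6`
is the arms-race coupling: at the young-family methylation level it
suppresses mobilisation several-fold. Candidate insertion points are
uniform over the genome and accepted with probability `exon_penalty`
(default 0.36, matching a 2.8-fold exonic deficit) when they fall in an
exon. Insertion sequences are windows of the family consensus at SV-age
divergence; carriers are drawn per SV with at least one carrier, and the
VCF conserves the truth-table SV count exactly.

The genome is a deterministic layout of 8 contigs x 80 gene units (8 exons
of 400 bp, introns of 1200 bp, 80 kb intergenic — exonic fraction 3.5%),
identical across species; copies are placed on an anchor grid with a
guaranteed > 5 kb gap between neighbours so fragment linking has an
unambiguous ground truth, and each copy is split into 1–3 fragments
(geometric, mean 1.5) with 20–300 bp genomic gaps and contiguous consensus
spans (descending along the genome on the minus strand). CpG records are
emitted inside copies at 0.02 sites/bp with the family's methylation
fraction, plus 150,000 background sites per species at the background
fraction (rejected out of copy intervals); coverage is uniform on 5–60x to
exercise the coverage filter, and the per-site probability is drawn above
or below the 0.80 call threshold according to the site's true state, so
family-level percentages are unbiased for the generating fractions.

Horizontal transfer is injected on demand: a family whose native range
ends at least two rings short of the chain's end gains recent,
near-full-length copies in a species at least two rings deeper, and is
flagged in the truth table; transfers into the adjacent ring are
phylogenetically invisible to any presence/absence ladder — the same
caveat real analyses carry — and are therefore not drawn.

## What the defaults encode, and what passing tests show

The default configuration is the package's reference study condition,
fixed after a 20-seed design study and not tuned per seed: a nominal 200
families, six in-group species, suppression strong enough that the
methylation–spreading correlation is negative overall and most negative in
the youngest age group, erosion strong enough that mean copy length
declines monotonically across the five age groups, and an exonic deficit
matching the generating penalty. Under these conditions the end-to-end
suite checks that the pipeline *recovers* the encoded structure: age
assignment at better than 95% accuracy (100% in practice without
transfers), unbiased methylation estimates, complete SV family recovery at
the simulated divergences, and the four arms-race signatures above.

Passing these tests demonstrates that the measurement chain is correct and
unbiased on data with known structure. It does not demonstrate that real
termite genomes satisfy the model: real TE libraries have indel-rich,
low-complexity, nested copies; real methylation has genomic context
effects; real SV calling has genotyping error; and real superfamilies do
carry lineage signal. Those are properties of data, not of the
measurement; the pipeline's parameters (gap tolerances, identity
thresholds, call boundaries) are all exposed precisely so they can be
re-examined against real inputs.

## Numerical choices and degenerate inputs

Saturated K2P copies are excluded rather than clamped. Constant ANCOVA
responses report F = 0 rather than 0/0. Zero-count region rates report an
infinite ratio plus the Haldane-corrected alternative. Families with zero
reference abundance are excluded from spreading efficiency with a message,
never a crash. Representative and best-hit ties break deterministically
(longest, then lexicographically smallest id). Clustering is order-
invariant by construction. All randomness flows from a single integer
seed; identical configs produce byte-identical cohort files.

## Problem sizes

The reference cohort (~200 families, ~18,000 copies over six species,
~1,400 SV loci, ~1.2 M CpG records) simulates in about 20 s and runs
through the whole pipeline in about 40 s on one core; the test suite,
including the end-to-end acceptance run, completes in a few minutes. These
sizes were chosen to exercise every filter with comfortable statistical
power while keeping the full analysis interactive.

# Known limitations

* The seed-and-extend SV annotator handles substitution divergence
  (with a Smith–Waterman fallback) but is not tuned for heavily
  indel-fragmented insertions; real-data use should widen `min_cov`
  sensitivity checks.
* The ladder classifier dates families by distribution, not by sequence
  divergence; horizontal transfers into the adjacent clade ring are
  undetectable by construction.
* KD landscape classes depend on heuristic mode detection; borderline
  families should be inspected, which is why per-family histograms are
  emitted alongside the classes.
* The simulator draws superfamilies independently of phylogeny and places
  copies without nesting; cross-genome ordination/congruence analyses on
  synthetic data therefore probe machinery, not biology.
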