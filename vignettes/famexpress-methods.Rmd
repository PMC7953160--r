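---
title: "Gene-family comparative transcriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family comparative transcriptomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famexpress)
```

## Why families

Comparing transcriptomes across species fails gene-by-gene wherever
orthology is many-to-many or a gene is lineage-specific. `famexpress`
therefore compares **ortholog gene families**: sets of homologous genes
across species, built from pairwise protein similarity. A family is the
unit of quantification, differential expression and functional inference.
Families present in only the focal species are the natural place to look
for lineage-specific biology; families with many same-annotation copies
(replicated genes) flag amplified functions; families with exactly one gene
per genome feed supergene concatenation for phylogenetics.

## Family construction

Pairwise protein hits are admitted when the E-value is strictly below
1e-5 and both alignment identity (> 50%) and coverage (> 75%) strictly
exceed their thresholds. Coverage is alignment span over the *full* protein
length, and it is required on **both** partners. "Coverage" of a pairwise
alignment is inherently ambiguous — one-sided coverage admits asymmetric
fragment hits, which drag fragments into full-length families; requiring
both sides keeps families symmetric, and a flag (`min_coverage_pct`)
exposes the threshold.

The filtered graph, weighted by bitscore, is clustered with Markov
clustering (MCL): alternate expansion (matrix squaring) and inflation
(entry-wise power 2 with column renormalization) until the flow matrix is
stable (max column change < 1e-8, cap 100 iterations, entries below 1e-5
pruned). Clusters are read off the support of the limiting matrix; nodes
drawn by overlapping attractor systems are merged, and families are
relabelled by their lexicographically smallest gene id so output is
deterministic regardless of input order. Self-loops are set to each node's
maximum incident weight, the usual MCL regularization. Genes with no
surviving edges become singleton families — single-gene families are
legitimate and, for species-specific biology, common.

This is a deliberate simplification of two-stage ortholog pipelines that
first classify in-/out-paralogs per species pair and then cluster: the
threshold-filter + MCL core is the family-defining step, fully specified
and testable, at the cost of not reproducing the pairwise
in-paralog bootstrap. On disjoint-clique graphs MCL provably reduces to
connected components, which is the anchor for the oracle tests.

Coordinates are read from GFF3 as 1-based inclusive and stored 0-based
half-open throughout. A gene is telomere-proximal when
`min(start, L − end) < 10000` on its chromosome of length `L`. Replicated
genes are same-family, same-species members whose annotation strings match
after case-folding and whitespace collapsing — the data provide no
principled fuzzier rule, so none is invented.

## Expression model

Gene-level FPKM is `count * 1e9 / (length_bp * library_size)`. Family
expression is the **sum** of member FPKM; family counts are the sum of
member counts. Sums, not means: the family is treated as one expandable
locus, so copy-number gains show up as expression gains. Replicates at a
time point are averaged for FPKM and pooled (counts and library sizes
summed) for the count-based statistic, which needs raw counts to model
uncertainty.

## The uncertainty-penalized fold change

Single-replicate count data make the raw log2 ratio unreliable at low
counts. The statistic used here places a Gamma posterior on each
condition's expression rate under a Poisson likelihood with a flat prior:

  λ ~ Gamma(count + 1, library_size)

For D = log₂(λ_A / λ_B), let q_lo and q_hi be the 1% and 99% posterior
quantiles. The statistic is q_lo if q_lo > 0, q_hi if q_hi < 0, and 0 when
the interval spans zero — the credible-interval boundary nearer zero, i.e.
a fold change the data can actually support. |statistic| ≥ 1 calls a
family differentially expressed (up at ≥ 1, down at ≤ −1). The tail mass
(`credibility = 0.01`) matches the conservative default behavior of
credible-interval fold-change tools; the raw companion value uses a
pseudocount of 1 on both conditions so it stays finite at zero counts.

Quantiles are Monte-Carlo (default 10⁴ draws) rather than closed-form, by
inverse-CDF transform of common uniforms: `qgamma(u, count + 1, lib)`.
This coupling makes the statistic *exactly* monotone in `count_a` and
deterministic given the seed, and is simple enough to verify against an
independent 10⁶-draw `rgamma` oracle. Key properties, all tested: zero for
equal counts at equal depth; |statistic| ≤ |raw| + ε (shrinkage toward 0);
antisymmetry under condition swap; convergence to the raw log2 ratio as
counts grow (the posterior concentrates).

The statistic is computed on family-summed **counts** (the uncertainty
model needs counts), while family FPKM drives correlation and reporting.
Both are exposed; summed counts are the default.

## Trajectories, clustering, function transfer

Each family's trajectory is the fold-change statistic of every later time
point against the 1 h reference (default grid 1, 4, 6, 12, 24, 48, 72 h).
Families differential at ≥ 1 time point in either species enter
clustering; the feature vector is the focal species' trajectory followed
by the partner's (12 values at the default grid). Features are fold-change
values, not raw FPKM — the trajectory heatmaps this reproduces are colored
by fold change, and fold-change space removes absolute-abundance scale.

K-means uses k-means++ seeding and Lloyd iterations, best of 25 restarts
by inertia, k = 12 by default. Clusters that empty mid-iteration are
re-seeded from the point farthest from its centroid; when every point
already sits on its centroid (identical inputs) the empty cluster is
simply dropped rather than force-split. Per-iteration inertia is recorded
and is provably non-increasing. Determinism comes from deriving each
restart's seed from the master seed.

Function transfer for unannotated species-specific families is
guilt-by-association: Pearson r between the family's FPKM profile and
every annotated gene's profile over all seven time points; the best gene
wins if r > 0.8, ties broken to the smallest gene id (logged).
Correlation is computed on untransformed FPKM — the literal reading of
summed-FPKM profiles — with a `log_transform` switch for log2(FPKM + 1).
All seven time points are used, including the reference: the profile is
the expression trajectory, not the fold-change vector. Zero-variance
profiles have no defined r and are skipped with a message.

Phase-matched trends compare each species in its own fast-growing window
(defaults: focal 12 h vs 6 h, partner 24 h vs 12 h) because the two
species traverse growth phases at different clock times; the windows are
configuration, derived from growth curves, not constants. Each species'
fold change reduces to up/flat/down at the two-fold thresholds, giving a
3 × 3 category table whose cells partition the shared families.

## Enrichment

Over-representation uses the exact upper-tail hypergeometric probability
P(X ≥ k) for k hits among n set genes, K term genes, N background genes
(`phyper(k − 1, K, N − K, n, lower.tail = FALSE)`). The default reports
raw p < 0.05 with no multiple-testing correction, mirroring common
practice in comparative surveys; a Benjamini–Hochberg flag is provided.
The background defaults to all genes present in any family and is
configurable. No GO-graph ancestor propagation is done.

One calibration point worth making explicit: the hypergeometric null
samples *genes* independently, but a family-to-cluster label permutation
exchanges whole families, so multi-gene families move as correlated blocks.
Gene-level tests under such a permutation are anticonservative. The
package's permutation control therefore operates on family-level units,
where label permutation is exactly the test's sampling model.

## The synthetic generator

The generator emulates the study design the package targets: a small clade
of genomes for the family layer (default 4 species, 200 families: 40
universal single-copy, 15 focal-specific of which 5 multi-gene, 20
multi-copy with 2–4 focal copies, 125 shared across proper subsets), and a
two-species, 7-time-point expression layer. Within-family similarity
edges are drawn to pass the homology filters (identity 55–95, coverage
85–100, E-value ≤ 1e-10); 5% decoy cross-family edges each fail at least
one filter. Homolog lengths vary only ~3% within a family so that
coverages survive the BLAST-tabular round trip through alignment lengths.

Counts follow archetypal trajectories — flat, late-up (+amplitude from
12 h), late-down, transient (4–6 h) — with log2 amplitude 3 (8-fold) and
negative-binomial noise (size 10; Poisson is the large-size limit, which
the tests exploit). Library size is 2 × 10⁶ per sample and baseline family
means are 100–400 counts, scaled down from sequencing-scale depth so the
default dataset builds in seconds while keeping count-noise regimes
realistic. Focal-specific families track a designated annotated gene's
latent log2 profile (s.d. 1.2), planting recoverable co-expression
partners; partner genes are drawn from families absent in the second
expression species so the planted profiles never contaminate the
cross-species clustering truth. Each non-flat archetype's member genes
carry a planted GO term, plus 20 random background terms.

What the generator does **not** emulate: read-level artifacts (mapping
bias, multi-mapping), between-sample library composition effects,
overdispersion heterogeneity across genes, correlated evolution of
similarity scores, and GO-term hierarchy. Passing recovery tests on this
data demonstrates the machinery is correct and calibrated under the
planted model, not that real data meet those assumptions.

For clustering recovery specifically, a feature-level simulator
(`simulate_trajectory_features`) plants archetype patterns plus Gaussian
noise (s.d. 0.25) directly in fold-change space, and a profile-level
simulator (`simulate_coexpression_profiles`) plants 20 family/partner
pairs at population correlation 0.95 among 50 decoy genes — with 7 time
points, sample correlations scatter widely around 0.95, which is exactly
the regime the r > 0.8 threshold is meant to tolerate.

## Numerical and degenerate-input choices

- MCL: pruning 1e-5 per column, convergence 1e-8, 100-iteration cap;
  dead columns restored as self-attractors; deterministic relabelling.
- Fold change: the seed for each comparison is derived deterministically
  from the master seed and the comparison's position in sorted order, so
  results are independent of input row order; the caller's RNG stream is
  saved and restored around every stochastic call.
- k-means: empty-cluster reseed from the farthest point; identical-input
  collapse leaves one populated cluster with inertia 0.
- Enrichment: terms with zero hits are omitted (their upper-tail p is 1);
  empty annotations never match each other for copy-number grouping.
- Supergene concatenation orders blocks lexicographically by family id, so
  the output is invariant to input order; ragged blocks and missing
  species are errors naming the offending block.

## Problem sizes

The default synthetic dataset (≈ 650 genes, 200 families, 2 × 7 samples)
runs the full pipeline in under a minute on one core; the Monte-Carlo
fold-change statistic dominates (≈ 2000 comparisons × 10⁴ draws). These
sizes were chosen so the whole test suite exercises every stage, including
two full pipeline runs, at desk scale. Real datasets (thousands of
families, deeper libraries) scale linearly in comparisons and draws.

## Known limitations

- The family step does not reproduce in-/out-paralog classification;
  families may split or lump differently than two-stage ortholog pipelines
  near the similarity thresholds.
- The fold-change statistic assumes Poisson sampling given the rate; real
  RNA-seq overdispersion beyond the posterior's width is not modeled
  (there are no replicates to estimate it from).
- Function transfer by correlation inherits all guilt-by-association
  caveats: co-expression is evidence of shared regulation, not function.
- Raw-p enrichment at 0.05 with many terms will contain false positives;
  use the BH flag for any confirmatory claim.
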