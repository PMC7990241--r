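---
title: "Methods behind metabopipe: validation, imputation, pretreatment, statistics and fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind metabopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopipe)
```

This vignette is the package's own account of the models and numerical
choices behind each stage of the pipeline: what is computed, under which
assumptions, which parameters matter, and where a genuinely open design
question was settled one way rather than another.

## The data model

The unit of analysis is a feature table: samples in rows, metabolites in
columns, one column carrying a unique sample identifier and one a group
label for comparisons. Additional columns can be sample metadata
("factor"), a sample weight/volume used for normalization, or masked
(excluded from analysis but retained). After role assignment and
validation, the table decomposes into three pieces — the numeric
measurement matrix, per-sample metadata, per-metabolite metadata — which is
the shape every downstream function consumes.

Validation is deliberately non-throwing: problems are returned as an
ordered report of coded items with row/column locators (0 errors means
analysis-ready; warnings never block). The missing-data thresholds default
to 25% per group and 25% overall, and the low-variance warning floor to
1e-8; none of these is canonical, all are arguments of
`validation_config()`. Text cells equal to the empty string, `NA`, or
`NaN` (case-insensitive) denote missing values; any other non-numeric text
in a measurement column is an error, because silently coercing it would
hide data-entry faults.

## Missingness classification and imputation

Metabolomics missingness has two canonical mechanisms. Values censored
below a detection limit go missing *because they are low* (MNAR); values
lost to sporadic technical faults go missing independently of their
magnitude (MCAR). The classifier uses only the pattern of holes and the
group structure — never the observed values — so it cannot be confounded by
the intensity distribution: a metabolite is **MNAR** when its missing
fraction within at least one group reaches `mnar_group_threshold`
(default 0.70), **MCAR** when it has holes but no group crosses the
threshold, and **complete** otherwise. The 0.70 default reflects the common
heuristic that near-total within-group loss indicates censoring; it is an
argument, not a constant.

MNAR fills substitute a below-detection surrogate: zero, or half of that
metabolite's smallest *observed* value (per-metabolite, not global: the
detection limit is metabolite-specific). MCAR fills borrow strength from
the rest of the matrix:

* *mean* / *median* of the observed column;
* *k-nearest-neighbour* (default k = 10): donors must be observed at the
  target metabolite; distances are Euclidean over mutually observed
  metabolites after dividing each column by its observed mean, so
  high-abundance metabolites do not dominate the metric; the imputed value
  is the donors' average;
* *iterative random forest* (default): missing cells start at column
  means, then each incomplete metabolite is regressed on all others with a
  random forest (100 trees) and its missing cells replaced by predictions,
  sweeping most-complete columns first, until the relative L2 change of
  the imputed cells drops below 1e-3 or 10 sweeps elapse.

All stochastic methods consume a single integer seed; identical seed,
identical output. Observed cells are never altered, and a metabolite with
no observed value at all falls back to zero fill with a warning, since any
value-dependent rule is undefined there.

## Pretreatment

The pipeline order is fixed: **normalize → transform → scale**. Sample-wise
normalization must see raw (or mass-corrected) totals, transformation must
precede scaling because scaling assumes roughly symmetric noise, and no
reordering is exposed.

* Normalization: row sums to a constant (default 100), to a reference
  sample's total, or division by a sample mass/volume column; `minmax`
  instead maps each metabolite column affinely onto [0, 1] — a column-wise
  reading, since the other options are already sample-wise and a row-wise
  min-max would destroy the compositional meaning of a sample.
* Transformation: log10, log2, square root, cube root. Negatives are
  always an error under log and square root. Zeros are fine under the
  roots; under the logs they follow an explicit pseudo-count policy whose
  default is *error* — offsetting is opted into, either as half the
  smallest strictly positive matrix value or as a fixed constant, because
  a silent offset changes fold relationships.
* Scaling, per metabolite with mean m, sample sd s (n−1 denominator
  throughout) and range r: autoscale (x−m)/s, Pareto (x−m)/√s, range
  (x−m)/r, vast ((x−m)/s)·(m/s), level (x−m)/m. Each method's
  precondition (s > 0, r > 0, m ≠ 0 as applicable) raises an error naming
  the offending column. These definitions give checkable identities —
  autoscaled columns have mean 0 and sd 1, Pareto-scaled variance equals
  the input sd, vast-scaled sd equals |m/s| — which the test suite asserts
  to 1e-9.

## Univariate statistics

For two groups each metabolite gets a two-sided Wilcoxon rank-sum p-value,
computed on the exact null distribution whenever both groups have at most
25 samples and the pooled values are tie-free, and by normal approximation
with continuity and tie correction otherwise. The exact path is verified in
the tests against an independent oracle that enumerates every assignment of
the pooled ranks.

For three or more groups a one-way fixed-effects ANOVA is followed
automatically by Tukey–Kramer HSD p-values for every pair, using the
studentized range distribution with the pooled within-group variance (the
Kramer form handles unequal group sizes). When the pooled within-group
variance is zero the p-values are undefined and flagged rather than forced.
For k = 2 the Tukey p reduces algebraically to the pooled-variance t-test p
(q = √2·|t|), which the tests exploit as a closed-form cross-check.

Fold changes are log2 ratios of arithmetic group means taken on the
normalized, *untransformed* scale — log or power transforms and any scaling
would distort the ratio a biologist reads off a volcano plot. Means that
are not strictly positive leave the fold change undefined and flagged.
Volcano selection requires both |log2FC| ≥ 1 and p ≤ 0.05 by default; with
more than two groups the p for the chosen pair is the Tukey pairwise p, so
the volcano remains a pairwise statement. Raw p-values drive selection; a
Benjamini–Hochberg adjusted column is emitted alongside, clearly labelled,
for users who want it.

## PCA, clustering, networks

PCA is the SVD of the column-centered matrix: scores are projections,
loadings right singular vectors, explained-variance fractions the squared
singular values over their total. Since singular vectors are sign-ambiguous,
each loading column is flipped so its largest-magnitude entry is positive,
making results run-to-run identical.

Hierarchical clustering (for heatmap ordering) offers Euclidean or
correlation (1 − r) distances with Ward, average or complete linkage; Ward
uses the squared-distance `ward.D2` form. The implementation delegates to
`stats::hclust`, which is deterministic for a given input order; when merge
distances tie, its internal ordering decides, which we accept as the
determinism contract rather than imposing a bespoke lexicographic
tie-break. Clustering can be toggled off, returning the identity leaf
order. Trees export as Newick with branch lengths derived from merge
heights.

Correlation networks connect metabolite pairs whose |r| (Pearson, Spearman
or Kendall tau-b) reaches a threshold; the signed coefficient is kept for
colouring, its magnitude becomes the edge weight, and node annotations
(data source, significance) travel with the network into node-link JSON.
Correlation p-values are intentionally not computed — thresholding is on
the coefficient. Layout is presentation, not computation: `autoplot()`
offers a seeded force-directed rendering, but the exported artifact is the
graph itself.

## Multi-platform fusion

Blocks are matched by exact, case-sensitive sample-ID equality (no fuzzy
matching — silent near-matches are worse than an explicit error), keeping
the first block's order. Three merges share that row set:

* *concatenation* keeps every feature column, prefixing colliding names
  with the block label;
* *PCA score fusion* replaces each block by its PCA scores. By default all
  components are kept (no information loss); a cumulative
  explained-variance cutoff is exposed for users who want only the major
  effects — the genuinely open choice between "keep everything" and
  "common effects only" is resolved in favour of keep-everything because
  it is the non-destructive default. "Normalized scores" is interpreted as
  unit-sample-sd score columns, putting platforms on a common footing.
* *multi-block weighting* centers each block and divides it by its first
  singular value, so every block's dominant direction has identical
  length in the grand table and no platform dominates the joint PCA.
  Centering precedes the SVD because an uncentered first singular value
  mostly measures column means, not structure.

Every fused column records its source block and original feature (or
component index), and fused tables are ordinary measurement tables for the
statistics and network modules, with provenance available as the "data
source" annotation.

## The synthetic-data generator

The generator emulates the structures the pipeline must handle: log-normal
intensities with per-metabolite abundances spread over ±2 natural-log units
(a wide dynamic range across the panel); within-metabolite biological noise
with log-sd 0.4 (~40% coefficient of variation, typical of across-subject
variation in metabolomics panels); multiplicative group effects on a chosen
number of differential metabolites; correlated metabolite blocks driven by
shared latent factors at a configurable within-block correlation (default
0.7); per-platform magnitude scales; and hole injection where MCAR removes
cells independently at a given rate and MNAR censors a metabolite entirely
within a named group. Total within-group censoring (rather than partial
left-censoring) is used for MNAR so the classifier's expected label is
forced by construction and agreement can be asserted exactly.

Randomness derives from one master seed through per-metabolite and
per-stage sub-seeds, so enlarging the panel never changes earlier columns.

What the generator does *not* emulate — heteroscedastic technical noise,
batch effects, partial left-censoring at a soft detection limit, non-normal
log intensities, platform-specific peak-picking artifacts — bounds what
passing tests show: they certify the algebra and the algorithms under clean
log-normal conditions, not performance on any given instrument's quirks.
The partial-censoring questions can still be explored manually by injecting
holes with custom masks.

## Problem sizes and numerical choices

The test and acceptance workloads were sized to be decisive yet quick: the
null type-I check uses 2000 metabolites at n = 10 per group; the imputation
benchmark 20 replicates of 20 × 12 correlated matrices with 10% MCAR holes;
the end-to-end recovery run 500 metabolites (50 differential, 4-fold,
n = 20 per group); the exact-Wilcoxon sweep all group-size pairs up to 8,
against full enumeration. Tolerances follow the quantity's nature: 1e-9 for
algebraic scaling identities, 1e-8 for the Tukey/t closed-form equivalence
(the accuracy of the studentized-range distribution function), interval
checks for stochastic rates.

Degenerate inputs are handled loudly: empty tables, all-missing
metabolites, zero row sums, zero variance columns, constant blocks and
empty sample intersections all raise (or warn) with the offending item
named, rather than producing NaNs downstream.

## Known limitations

Single imputation only — no multiple imputation, so downstream variance is
slightly understated. The Wilcoxon exact path is disabled by ties rather
than using exact tie-handling. Tukey HSD assumes homoscedastic groups.
Kendall networks are quadratic in samples per pair. Fusion requires
complete, pre-treated blocks and exact ID agreement. None of these blocks
the intended use: a reproducible, scriptable backend for multi-platform
feature-table analysis.
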