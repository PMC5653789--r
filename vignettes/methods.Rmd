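---
title: "Methods: concordance, attribution and synergy scoring in concordia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance, attribution and synergy scoring in concordia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordia)
```

`concordia` chains five statistical stages: per-gene differential
expression, directional set overlap, gene-set attribution, rank
correlation of response profiles, and qPCR synergy scoring. This
vignette documents the model behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic validation
data do and do not establish.

## Differential expression

Each tissue is a genes × samples matrix of log2 expression with a
binary case/control labelling. Per gene, `welch_contrast()` computes
the case-minus-control mean difference (the log2 fold-change: a
difference of log2 means is the log of the ratio of geometric means),
the Welch unequal-variance *t* statistic with Satterthwaite degrees of
freedom, a two-sided p, and a Benjamini–Hochberg q over all genes.

Assumptions: samples are independent, gene-wise residuals roughly
Gaussian on the log2 scale, and each group has at least two samples
(hard error otherwise). The Welch form was preferred over pooled-
variance Student because case tissue is typically more heterogeneous
than control tissue; `var_equal = TRUE` restores the pooled test. No
empirical-Bayes variance moderation is applied: moderation changes DEG
counts invisibly and the package's contract is that the thresholded
counts be exactly reproducible from the stated test. Degenerate genes
(zero variance in both groups) get t = 0, p = 1 when the means agree
and the smallest representable p when they differ, keeping p in (0, 1].

`call_degs()` applies **strict** inequalities — log2FC > log2(2) and
q < 0.05 by default — so a gene sitting exactly on either boundary is
excluded. Both thresholds are linear-scale parameters of the call, and
tightening either can only remove genes (a property the tests assert).

## Directional concordance

`directional_overlap()` first restricts both studies to the
intersection of their tested universes. This choice is load-bearing:
the overlap p-value is monotone in the universe size, and counting
genes only measurable on one platform would inflate significance. The
intersection size is therefore logged and carried in every report.

On that universe, the up/up (and down/down) overlap is scored with the
upper-tail hypergeometric probability

P[X ≥ k],  X ~ Hypergeom(N, K, n),

with N the universe, n and K the two set sizes and k the overlap —
equivalently a one-sided Fisher exact test. `hypergeom_upper_tail()`
delegates the tail to `phyper()`, which accumulates in log space and is
accurate at the extreme tails these analyses reach (p below 1e-100 is
routine with planted effects); the test suite checks it against
exhaustive subset enumeration for every valid tuple with N ≤ 12 at
1e-12 relative error. The overlap percentage is reported relative to
study A's restricted set, which is deliberately asymmetric ("x% of the
A-up genes were also up in B"); the count k and the p-value are
symmetric in the two studies.

No up/down discordance test is offered: the analysis question is
whether the two diseases share direction, not whether they oppose.

## Attribution against a stimulation compendium

The compendium is a GMT file with two entries per treatment,
`<name>_induced` and `<name>_repressed`. For the shared up-regulated
set S, `signed_signature_stat()` tests S against each side separately
with the same hypergeometric tail (signature sets are first intersected
with the universe), then folds the pair into one signed scalar:

- magnitude: −log10 of the smaller of the two p-values;
- sign: + if the induced side matches at least as strongly (ties go to
  +), − otherwise;
- two-direction p: min(1, 2 · min(p_induced, p_repressed)), a
  Bonferroni doubling reflecting that each treatment is tried in two
  directions.

The signed −log10(min p) form was one of several defensible choices
(a signed z would serve equally); it is isolated in a single function
so an alternative can be swapped without touching the ranking.
`rank_treatments()` adds BH q-values over the doubled p-values and
imposes a deterministic total order: q, then p, then |statistic|
descending, then treatment id lexicographically — so the ranking is
invariant to input order. Treatments whose signatures vanish after
universe restriction are flagged degenerate (statistic 0, p 1) rather
than dropped, keeping the BH denominator honest.

Term enrichment (`enrich_terms()`) uses the same tail against a flat
gene→term table and flags terms at **raw** p < 0.001 — no multiple-
testing correction at this stage, matching the convention of reporting
"n categories at P < 0.001". The annotation is flat by design: ontology
propagation is a preprocessing concern, and keeping the statistic on an
explicit table makes it exactly testable. Users with a real DAG should
pre-propagate annotations before building the table.

## Response-profile correlation

`fold_change_profile()` reduces a matrix to per-gene mean differences;
`spearman_correlation()` correlates two profiles over the genes they
share (exact string match, all shared genes by default — no
responsive-gene filter is applied unless the caller subsets the
profiles). ρ is the Pearson correlation of mid-ranks, the standard
tie-handling; p uses the two-sided t approximation
t = ρ·√((n−2)/(1−ρ²)), which is accurate for the thousands-of-genes
profiles this stage is meant for and rough below n ≈ 10 — for n ≤ 8 an
exact permutation p over all n! orderings is available. ρ = ±1 returns
the smallest representable positive p rather than 0 to honor the
p ∈ (0, 1] contract. At least 4 shared genes are required.

## ΔΔCt quantification and synergy

`ddct_fold()` implements classic relative quantification with
amplification efficiency fixed at 2: per condition,
ΔCt = mean Ct(target) − mean Ct(reference); the fold-change versus the
control condition is 2^−ΔΔCt. Averaging Ct values arithmetically is
averaging folds geometrically, which is the right central tendency for
a log-scale quantity; when replicate indices align across all four
series the per-replicate ΔΔCt folds are returned too, and their
geometric mean equals the headline fold by construction. The method is
invariant to any condition-wide additive Ct shift applied to target and
reference alike (loading/input artifacts), a contract the tests assert.
Efficiency-corrected (Pfaffl-style) quantification is out of scope.

`synergy_index()` compares the observed combination fold to a null
expectation: `bliss_multiplicative` (default) expects fold_A · fold_B —
independent multiplicative action, i.e. additivity of ΔΔCt shifts —
and `additive_hsa` expects max(fold_A, fold_B), the highest-single-
agent model. The index is observed/expected; classification uses an
equality tolerance of 1e-9 on the index so that exact-arithmetic
additive cases are not misclassified by floating-point dust. No
hypothesis test is attached to the index — replicate-level uncertainty
is summarized instead by an optional percentile bootstrap CI in
`ct_synergy()` — because fold-ratio inference without an error model of
the plate layout would be false precision.

Worked arithmetic: single-agent folds of 600 and 60 give a
multiplicative expectation of 36,000; an observed combination fold of
95,000 yields an index of 2.64, classified synergistic.

## What the synthetic generator emulates

`generate_two_tissue_study()` builds the full input bundle with known
truth:

- **Baseline**: per-gene log2 baseline ~ N(7, 2) — a log-normal
  expression distribution on the linear scale, the simplest model under
  which the Welch/BH machinery is exactly appropriate.
- **Compendium**: 42 treatments by default, 100-gene signatures split
  70% induced / 30% repressed, sampled independently per treatment so
  signatures overlap (as real cytokine response programs do); a
  `disjoint` switch partitions the universe instead. The 70/30 split is
  a package choice — stimulation experiments typically induce more
  genes than they repress at these thresholds — and is configurable.
- **Planting**: the first `n_driver_treatments` treatments (named
  "IFN-g", "TNF-a" by default) are drivers: their signature genes get a
  shared log2 effect of log2 3 ≈ 1.58 in the case group of *both*
  tissues, signed by membership direction. When overlapping driver
  signatures disagree about a gene, the first-listed driver wins, so
  every planted gene has one consistent direction in both tissues.
- **Background**: 5% of the remaining genes per tissue get
  tissue-private effects (random sign, magnitude uniform on
  log2 1.5–2.0), independently in each tissue, so the concordance
  stage faces realistic non-shared differential expression.
- **Noise**: gene-wise independent N(0, 0.5²) on the log2 scale.
- **Cohorts**: 13 samples per group in tissue 1 and 16 per group in
  tissue 2 — the scale of the carotid-plaque cohorts (13 early / 16
  advanced) this design emulates.
- **Annotation**: 50 random 20–60-gene terms plus one planted term
  covering the planted induced genes.
- **Seeding**: one master seed expands into fixed per-component
  substreams, so the compendium, each tissue, the annotation and the
  Ct table are individually reproducible.

The generator deliberately does **not** model probe-level microarray
structure, count noise (negative binomial), batch effects, correlated
genes, or platform differences between the two tissues. Passing the
recovery tests therefore shows the pipeline's statistics are correct
and well calibrated under their own assumptions — it does not show
robustness to the violations real cross-platform data bring
(correlation between genes chiefly makes the overlap p-value
anti-conservative; treat extreme p-values on real data as ordering
evidence, not literal error rates).

`generate_ct_experiment()` plants a four-condition layout (control, A,
B, A+B) in Ct space: a Ct decrease of d cycles is a 2^d-fold increase,
and the combination receives an extra `interaction_dct` shift so the
Bliss index recovers exactly 2^interaction_dct in the noise-free case —
an exact closure test of the whole ΔΔCt → synergy path.

## Calibration under the null, and one interpretation choice

With no planted effects the per-gene Welch p-values are uniform (the
suite checks a KS test at α = 0.01 passes in ≥ 95 of 100 seeds) and BH
keeps the attribution stage near zero significant treatments. For the
concordance arm, note what "null" means end-to-end: with nothing
planted the FDR-thresholded DEG sets are almost always *empty*, the
overlap is k = 0 and p = 1, so the fraction of null runs with p < 0.05
sits near zero — at, not centered on, the nominal 5%. The suite
therefore asserts a no-anticonservatism bound (rate ≤ 0.05 plus its
binomial CI) for the end-to-end null, and checks genuine calibration of
the hypergeometric tail separately on random fixed-size sets, where the
discrete exact level can be computed and matched. Hypergeometric
p-values are discrete and hence conservative at any fixed cutoff;
this is inherent to exact tests on counts.

## Problem sizes used in validation

The shipped tests and the acceptance script run the generator at its
defaults (2000 genes, 42 treatments, 2 drivers, 13/16 per group) for
calibration (100 seeds) and driver recovery (50 seeds), smaller
universes (200–1000 genes) for structural unit tests, and exhaustive
enumeration up to N = 12 for the hypergeometric oracle — sizes chosen
so the full suite documents the statistics thoroughly while remaining
quick to run on a laptop.

## Known limitations

- Gene identifiers are matched as exact case-sensitive strings; alias
  resolution must happen upstream or set sizes silently shrink at the
  intersection step.
- The DEG model is two-group only: no paired designs, covariates, or
  limma-style linear models.
- The overlap test conditions on the DEG sets; it does not propagate
  DEG-calling uncertainty.
- The synergy index is descriptive; with n = 3 replicates a bootstrap
  CI is wide and should be read accordingly.
- Inputs are assumed gene-level; probe-to-gene collapsing is a
  documented precondition, not a feature.
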