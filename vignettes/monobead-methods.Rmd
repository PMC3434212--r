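---
title: "Methods: bead-level preprocessing, regularized differential expression, clustering and qPCR validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bead-level preprocessing, regularized differential expression, clustering and qPCR validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`monobead` implements a complete small-cohort transcriptome comparison
pipeline of the kind used to contrast circulating monocyte expression
profiles between a patient group and healthy controls, and within patients
before and after a short drug course. This vignette documents the statistical
model at each stage, the tunable parameters and their defaults, the design
choices made where the underlying methods literature leaves options open, and
what the synthetic-data generator does and does not emulate.

## Study design assumed throughout

The default design is 12 healthy controls and 18 patients sampled at
baseline, with 12 of the patients resampled after treatment (paired to their
own baselines). Arrays carry on the order of thousands to tens of thousands
of gene probes plus a set of negative-control probes, with tens of beads per
probe per array.

## Bead-level preprocessing

**Outlier removal.** For each probe on each array, beads outside
`median ± 2 × MAD` are removed, where MAD is the raw median absolute
deviation from the median, *without* the 1.4826 normal-consistency factor
(`mad_multiplier = 2`, unscaled — deliberately, since the rule is defined on
the raw MAD). Bounds are inclusive. Under normal noise this rule trims about
18% of beads; it is aggressive by design and targets the heavy-tailed gross
errors (×4 / ×¼ bead failures) that bead arrays produce. When the MAD is
exactly zero the rule read literally retains only beads equal to the median;
`mad_zero_policy = "strict"` (default, with a warning) applies that reading,
`"retain_all"` keeps every bead.

**Summarization.** The probe value is the arithmetic mean of retained beads.
A probe whose beads were all removed is flagged missing for that array and
later imputed at the array minimum (logged).

**Detection.** Each probe is called *present* when a one-sided Welch t-test
finds its retained bead intensities greater than the pooled, outlier-filtered
negative-control beads of the same array at `alpha = 0.05`. Whether the
original instrument software tested bead-level or summarized values is not
documented; we test bead-level values against the pooled bead-level negative
controls, which uses all available replication.

A property worth knowing: because detection runs on *truncated* bead sets,
within-probe variance estimates are biased low and the null detection rate
on pure-background probes runs at roughly 3× the nominal alpha. The tests
document this; with the filter disabled the Welch call is calibrated. The
inflation is harmless downstream because activity calls require presence in
at least 8 of 12 (or 13 of 18) samples of a group, which background probes
essentially never reach per group — though it does enlarge the union-rule
assessed set beyond the truly expressed fraction (about 0.61 when half the
probes are expressed, at default settings).

**Group activity.** A probe is *transcriptionally active* in a group when
present in at least `k(n)` of its `n` samples, with the published thresholds
`k(12) = 8` and `k(18) = 13` hard-coded. No single standard proportion test
reproduces both printed thresholds, so for other group sizes we use the
smallest `k` whose one-sided Z-test against a null proportion of 0.5 (no
continuity correction) gives p < 0.05; the lookup values take precedence.
The *assessed* set for a two-group contrast is the union of the groups'
active probes; `assessed_probes(..., rule = "intersection")` gives the
stricter both-groups-active set used for variance comparisons (below).

## Normalization and differential expression

**Log2-quantile normalization.** Values are log2-transformed, then each
sample's sorted values are replaced by the across-sample means of the values
at the same rank. Tied values receive the mean of the reference values their
tied ranks span, so ranks are preserved and, absent ties, every sample ends
with the identical value multiset. The implementation is a dozen lines and
is cross-checked in the tests against `limma::normalizeQuantiles` on
tie-free data.

**Regularized (Cyber-t style) unpaired test.** With 12 vs 18 samples,
per-gene variance estimates are unstable; the test shrinks them toward a
local background. Genes are ordered by mean log2 expression; the background
variance `σ₀²` of a gene is the mean pooled variance over the `window_size`
(default 101, odd) nearest genes in that order, truncated at the ends. The
regularized pooled variance is

    s̃² = (confidence · σ₀² + (nA−1)sA² + (nB−1)sB²) / (confidence + nA + nB − 2)

with `confidence = 10` pseudo-observations by default (the canonical choice;
both parameters are exposed). This form reduces *exactly* to the ordinary
pooled variance as `confidence → 0`, which the tests verify to 1e−6 at
confidence 1e−9. Two-sided p-values use `nA + nB − 2 + 2·confidence − 2`
degrees of freedom. Genes whose background window has zero variance fall
back to the smallest positive gene variance (logged). Under a global-null
cohort of 5,000 genes the empirical fraction of p < 0.05 sits within
[0.035, 0.065].

**Paired test.** The pre/post contrast uses the standard paired t on
per-subject differences. Zero-variance differences are degenerate: p = 1
when the mean difference is zero, p = 0 otherwise (logged).

**Fold changes** are `2^(Δ mean log2)` on normalized data — the standard
convention consistent with testing on the log scale; `fold_change(A,B) ×
fold_change(B,A) = 1` exactly. No multiple-testing correction is applied in
the primary outputs (deliberate, matching the small-cohort design this
pipeline targets); `add_fdr()` appends a Benjamini–Hochberg column on
request.

**Threshold grid.** `threshold_count_table()` counts genes at p < 0.05 /
0.01 / 0.001 / 0.0001 and at three combined significance-and-fold-change
cells (p<0.05 & FC<0.74 or >1.35; p<0.001 & FC<0.82 or >1.2; p<0.0001 &
FC<0.91 or >1.1), all with strict inequalities.

**CRP tertiles.** Baseline patients are sorted by CRP (ties broken by sample
id), split into tertiles of `floor(n/3)`, and the lowest and highest
tertiles are each tested against all controls with the regularized test on
the assessed set; the middle tertile is left out.

## Clustering and heterogeneity

**Ratio matrix.** Relative expression for the heat-map and clustering stage
is the linear-scale signal divided by the per-gene mean over baseline
samples ("signal" reads as linear intensity, so log2 matrices are
linearized first). The gene set is the significantly modulated genes of the
paired contrast.

**Clustering.** Average linkage (UPGMA) on Euclidean distances between
sample ratio profiles — the stock combination in expression heat-map tools;
the source description conflating "Euclidean distance" with "average-linkage
correlation" is resolved this way and not guessed further. Leaf order is
made deterministic: at every merge the subtree containing the
lexicographically smallest sample id goes left, so results are invariant to
input order.

**Adjacency score.** "Each treated patient clusters next to their own
baseline" is operationalized as the fraction of subjects whose two samples
occupy adjacent leaf positions — the strictest checkable reading of the
dendrogram phenomenon. With a per-subject signature sd of 1.0 (log2) and a
treatment effect sd of 0.05, adjacency is ≥ 11/12 in essentially every
simulated cohort.

**Per-sample heterogeneity.** Each sample is scored by the SD, over a gene
set, of its log2 ratio to the per-gene control mean (leave-self-out when
scoring a control, to avoid self-bias). A patient is flagged when its SD
exceeds `mean + flag_k · sd` of the control SDs (`flag_k = 2`; no cutoff is
documented in the source literature, so the multiplier is exposed). Two
methodological notes, both verified by simulation:

* *Gene set.* The analysis is defined on normally distributed log2 ratios.
  Near-background probes are not normally distributed and enter the
  union-rule assessed set partly *because* of extreme values in the very
  samples being scored, inflating patient SDs. The pipeline therefore scores
  heterogeneity on probes active in **both** compared groups
  (`rule = "intersection"`), where the activity call is effectively
  deterministic and introduces no selection.
* *Limits of the flag rule.* With only 12 reference controls, a
  `mean + 2·sd` threshold is a tolerance interval estimated from 12 values:
  even for patients exchangeable with controls, each has a ~1–3% chance of
  a false flag, so exact recovery of a planted heterogeneous set succeeds in
  roughly 80–90% of cohorts and cannot be driven to 100% by any
  implementation. This is a property of the rule, not of the code.

## qPCR validation arm

Replicates with amplification-curve quality below 0.65 are dropped and the
survivors averaged per (sample, gene); combinations losing all replicates
are reported missing. Reference-gene stability is computed two ways on the
four housekeeping candidates (GAPDH, RN18S, ACTB, RPL13A):

* **geNorm M** — mean over partner candidates of the SD across samples of
  the pairwise log2 ratio, on relative quantities `2^−(Ct − min Ct)` (the
  standard input transform); pairwise-complete with a minimum of 3 shared
  samples.
* **NormFinder-style stability** — candidate log-quantities are centered per
  sample on the candidate mean, then decomposed per group into an intergroup
  bias and an intragroup variance. Raw bias estimates are shrunken toward
  zero by `τ²/(τ² + se²)`, where `τ²` is the across-candidate moment
  estimate of true intergroup variance: a panel with no real group
  dependence is ranked purely by intragroup variation, while a genuinely
  group-shifted candidate keeps its bias and ranks worst. The full
  variance-decomposition refinements of the original model-based method are
  not reproduced; this package's estimator keeps its structure (sample
  centering, bias + variance combination) with the shrinkage above.

The selected reference is the geNorm winner; disagreement with NormFinder
triggers a warning, as on clean data both select the same gene.
Quantification is the pure `2^−ΔΔCt` model (no PCR-efficiency correction):
`ΔCt = Ct_target − Ct_reference` per sample, `ΔΔCt` the group-mean
difference, tested on the ΔCt scale (normality-friendlier than the fold
scale) by Welch or paired t as the design dictates.

## The synthetic cohort generator

`generate_cohort()` draws, on the log2 scale: a baseline level per gene
(expressed genes Uniform(6.5, 12), non-expressed at the negative-control
background of 5); a patient-group shift for DE genes with linear fold
changes Uniform(0.3, 1.7) (the small-fold regime typical of these cohorts);
a per-subject gene-wise signature N(0, 0.3²) shared by both timepoints; a
treatment shift N(0, 0.1²) per gene for post samples — except designated
contamination genes (haemoglobin analogues standing in for reticulocyte
carry-over), which get a fixed +log2(1.5); and extra N(0, sd²) noise for a
designated minority of heterogeneous patients (4 of 18 by default). Bead
intensities are `2^(level + N(0, 0.25²))` with 2% of beads multiplied by 4
or ¼; negative controls are drawn from the background distribution.
Generation is deterministic given `rng_seed` (a master stream draws
structure and per-sample sub-seeds). Patient signatures are gene-wise
independent — the simplest model that reproduces own-baseline clustering
when the signature dominates the treatment effect.

`generate_qpcr()` builds triplicate Ct plates for a panel of DE target genes
plus the four housekeeping candidates: `Ct = base − log2(rel. expression) +
sample offset + N(0, 0.15²)` per replicate, with a 5% QC-failure rate. The
housekeeping panel is variance-designed: GAPDH carries the smallest
per-sample noise (sd 0.05 vs 0.30–0.40 cycles), with no group shifts, so one
candidate is unambiguously most stable under both criteria.

**What the generator does not emulate:** spatial/scanner artifacts, probe
cross-hybridization, correlated gene modules (signatures are independent
across genes), clinical covariates beyond a lognormal CRP, or
amplification-curve shapes (quality scores are drawn directly). Passing
tests therefore demonstrate the statistical machinery under the declared
generative model, not robustness to every failure mode of real arrays.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full chain at sizes chosen
to exercise the statistics while staying desk-sized: 2,000 probes (100
negative controls, 30 beads) for the default cohort and determinism checks,
5,000 expressed genes for null calibration (10 beads), 6,000 probes for
heterogeneity recovery, and 300-probe cohorts for the qPCR arm; 10–20
simulated cohorts per stochastic property. All probe counts scale to the
25,528-probe regime of real arrays by configuration. Ties in quantile
normalization follow the spanned-rank-mean rule; interval bounds in the
bead filter are inclusive; strict inequalities are used in every
threshold-grid cell; CRP ties break by sample id; dendrogram orientation
breaks ties by smallest sample id.
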