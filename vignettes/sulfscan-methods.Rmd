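---
title: "Statistical methods behind sulfscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind sulfscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfscan)
```

`sulfscan` implements the statistical workflow used to characterize the
heparan sulfate 6-*O*-endosulfatases SULF1 and SULF2 across cancer cohorts:
differential expression, survival dichotomization, signature-correlation
enrichment, single-cell attribution, and patient-vs-xenograft comparison.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Differential expression

Expression enters on a log2 scale — log2(TPM+1), log2(RSEM+1), or proteomic
log2-ratios to an internal control — declared explicitly on every
`ExpressionMatrix`. Raw TPM must pass through `log2_transform()` first; the
package refuses to test a `tpm`-scale matrix rather than silently assume.

For paired designs the effect size is the mean of per-pair differences on
the log2 scale, which equals the difference of group means when all pairs
are complete. The default paired test is the Wilcoxon **signed-rank** test.
The rank-sum (Mann–Whitney) test applied to paired samples is also exposed
(`test = "rank_sum"`) because pan-cancer screens sometimes use it for
paired tissues; it ignores the pairing and is less powerful, but both
options are available so either convention can be reproduced. The paired
t-test serves proteomic log-ratio tables, where approximate normality of
per-pair differences is reasonable.

Wilcoxon p-values are exact (full conditional distribution) when n ≤ 25 and
the data are tie-free; with ties at n ≤ 12 the exact conditional
distribution is enumerated directly over sign assignments (or group
relabelings) of the mid-ranks; otherwise the normal approximation with
continuity correction and mid-rank variance adjustment applies. This makes
small fixtures exactly reproducible — e.g., six pairs with a constant
positive difference give the two-sided p of 2/2^6 = 0.03125.

Multiple testing uses the Benjamini–Hochberg step-up (`bh_fdr`, via
`stats::p.adjust`), the field default where a screen reports an "FDR"
column without naming a procedure. Significance calling is strict:
|log2FC| > 1 **and** FDR < 0.05, so a gene at exactly 2-fold is *not*
called. `stage_anova` is the classical fixed-effects one-way F-test across
tumor stages; stage groups with fewer than two samples are dropped with a
warning because they contribute no within-group variance.

## Survival analysis

Kaplan–Meier estimation, the two-group log-rank test and Cox
proportional-hazards fitting are standard (the `survival` package stands
behind these surfaces); the package's own contribution is the **constrained
minimal-p-value cutpoint** used to dichotomize continuous expression:

* every distinct observed expression value is a candidate threshold, with
  high defined as value **strictly greater** than the cutoff (well-defined
  under ties);
* thresholds leaving fewer than `ceiling(min_frac * n)` patients in either
  arm are inadmissible (`min_frac = 0.25` by default — each arm keeps at
  least a quarter of the cohort, which bounds the optimism of the search
  and guarantees interpretable groups);
* among admissible thresholds the one minimizing the log-rank p is
  returned; exact ties on p resolve toward the cutoff closest to the median
  and then the smaller value.

The scan is computed with a vectorized multi-threshold log-rank: risk-set
and event indicator matrices over distinct event times are multiplied
against the threshold-indicator matrix, giving every O, E and hypergeometric
V in two matrix products. The result is numerically identical to running
`survival::survdiff` per threshold (the test suite verifies this
exhaustively) but fast enough to repeat inside simulations.

The reported minimal p is deliberately **unadjusted** for the search, as is
conventional in the screens this package mirrors; because a minimal-p scan
inflates type-I error substantially, `minp_cutpoint(adjust_b = B)` offers a
permutation adjustment that re-runs the entire constrained search on B
label permutations and reports the add-one rank of the observed minimal p.

Cox models use Efron's tie correction (more accurate than Breslow with
tied event days), a convergence tolerance of 1e-9 and at most 100
iterations; non-convergence and suspected monotone likelihood (separation)
are flagged on the result rather than silently returned. Age enters as
continuous years, gender as 0/1; records with missing covariates are
dropped casewise with a logged count. Stage-stratified analysis repeats the
cutpoint search and the Cox fit inside the stage I/II and stage III/IV
subsets; a stratum below 8 patients is skipped with a warning since a
constrained scan on fewer patients cannot produce two meaningful arms.

## Signature correlation enrichment

`correlate_target` computes Pearson correlations between a target and every
other row using pairwise-complete samples — chosen because proteomic tables
are sparse across sample pairs, and flagged in logs because the effective n
then varies per gene; correlations with fewer than `min_overlap = 10`
complete pairs are set missing. The enrichment statistic is the plain mean
of signature-gene correlations; the null is built by drawing random
same-size subsets of the full correlation table (signature members
included, since a "randomly selected subset of proteins" naturally includes
them — a flag excludes them) and the one-sided add-one p-value
(1 + #{null ≥ obs})/(1 + B) can never be exactly zero. Raw correlations are
averaged rather than Fisher-z values, matching how such comparisons are
usually reported; the z-transform is exposed as an option and matters
little at |r| < 0.7. A two-sided alternative is available; the default is
one-sided because the scientific claim is a rightward shift of the
signature's correlations.

## Single-cell attribution

A cell is positive when its stored log2(TPM+1) value is strictly greater
than zero — i.e., any detected transcript — so positivity is invariant
under monotone rescaling of the values. Percentages are reported at integer
precision (as such figures are printed) while full precision is retained in
result tables. Between-cell-type comparisons use the Welch unequal-variance
t-test by default, since an unpaired t-test with hundreds of cells per type
and unequal spread is the realistic setting; the pooled test is exposed.
Per-patient positivity flags patients with fewer than 10 cells of the type,
whose percentages are unstable, without removing them.

## Patient-vs-PDX comparison

The paired comparison of primary tumors with their xenografts uses the
Wilcoxon signed-rank test — the paired member of the Wilcoxon family —
with zero differences dropped before ranking (standard practice, and what
makes small exact p-values reproducible). Medians are reported on the raw
TPM scale, and the pair counts in each direction (PDX below / above the
patient value) quantify how uniformly a stromal gene collapses after
engraftment.

## Synthetic-data generators

Each generator is a pure function of its parameters and seed, and a root
seed derives per-stage substreams (`substream_seed`) so one integer
reproduces a whole pipeline run. Defaults were chosen once to mirror the
magnitudes reported for the HNSC/pan-cancer setting this package serves:

* `gen_paired_cohort`: log2-scale normals around a baseline of 6 with
  per-measurement sigma 1 — typical spread of log2(RSEM+1) in bulk tissue —
  and planted per-gene fold-changes.
* `gen_survival_cohort`: log-normal expression; hazard
  `1e-3/day × exp(beta·[x > cutoff] + 0.2·age_std)`; independent
  exponential censoring at `5e-4/day`. These rates give median
  times of roughly two years and a ~2/3 event fraction, resembling a
  progression-free-interval endpoint.
* `gen_cell_population`: per cell type, positivity is Bernoulli and
  positive values are Normal(mu, sigma) truncated above zero on the
  log2(TPM+1) scale. The truncation means the realized positive-cell mean
  exceeds mu by sigma·phi(mu/sigma)/Phi(mu/sigma) (about +0.03 at mu = 2.3,
  sigma = 1); recovery tests account for this analytically. The default
  spec plants the fibroblast-high SULF1 / tumor-high SULF2 pattern: 14% of
  2,215 tumor cells positive for SULF1 (positive mean 1.232) versus 48% of
  1,440 fibroblasts (positive mean 2.291), and 63% of tumor cells positive
  for SULF2.
* `gen_signature_universe`: a single latent factor per sample; the target
  and each signature gene equal `loading·F + sqrt(1 − loading²)·noise`, so
  the expected target–signature correlation is `loading²` (0.36 at the
  default loading 0.6); background genes are independent noise, and all
  rows are standardized.
* `gen_pdx_pairs`: patient TPM is a tumor component plus a stromal
  component; the PDX keeps only the tumor component times a log-normal
  growth factor. The stromal-gene preset puts ~95% of the patient signal in
  stroma (patient median ≈ 52, PDX median ≈ 2); the tumor-intrinsic preset
  reverses the weights and adds ~2-fold expansion.

What these generators deliberately do **not** emulate: batch effects,
library-size artifacts, gene–gene correlation beyond the single latent
factor, non-proportional hazards, dropout structure of real scRNA-seq, or
mouse-read contamination of PDX libraries. Passing tests therefore
demonstrate that the statistics recover what they claim under their own
assumptions — not that those assumptions hold in any particular cohort.

## Problem sizes and calibration checks

The test suite exercises the code at sizes chosen to give adequate
statistical resolution while keeping a full run quick: exact-test oracles enumerate all
configurations at n ≤ 8; the cutpoint scan is verified against an
exhaustive independent scan on 50 random 20–50-patient cohorts and its
recovery measured over 100 replicates at n = 400 with a planted HR of 2.5;
Cox coefficients are checked against brute-force partial-likelihood
maximization on 20 small tie-free cohorts and CI coverage of a planted
HR = 2 over 200 replicates at n = 1,000; the permutation test's type-I
error is measured over 1,000 null datasets (B = 200) on a reduced
60-sample, 500-gene universe — size does not affect the validity being
tested — while power is checked once at the full published dimensions
(206-gene signature, 10,073-gene universe, B = 10,000); BH behaviour is
verified on hand-computed step-ups and 200 all-null simulations of 2,000
genes.

## Known limitations

* The minimal-p cutpoint is reported unadjusted by default; treat its p at
  face value only with an external validation cohort, or use `adjust_b`.
* Pairwise-complete correlations can mix effective sample sizes across
  genes; the per-gene overlap is reported so users can filter harder.
* `cox_fit` caps at numeric flags for separation; it does not implement
  penalized (Firth-type) fits.
* The generators' distributional families (normal/log-normal/truncated
  normal) are conveniences, not claims about real data.
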