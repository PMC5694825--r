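---
title: "Methods: predicting cognitive impairment from baseline connectome metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting cognitive impairment from baseline connectome metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectocast)
```

## The problem

Chemotherapy-treated breast cancer patients frequently develop lasting
cognitive impairment. connectocast implements an end-to-end analysis that
asks whether that outcome is predictable *before any treatment* from
resting-state functional connectivity: per-region clustering coefficients
from the baseline connectome, together with patient/medical covariates, are
fed into random-forest classifiers whose targets are impairment labels
derived from longitudinal neuropsychological testing. Because no raw imaging
or cognition data are distributed with studies of this design, the package
also ships a seeded synthetic-cohort generator that reproduces the
statistical structure each stage assumes, so every stage is testable offline.

## Impairment labeling

Five standardized test scores (RAVLT trials A1 and A6, CTMT trails 1 and 5,
COWA) are z-scored against the control group's mean and SD per test — by
default per test *and* timepoint; a baseline-only reference is available via
`match_timepoint = FALSE`, since normative practice varies and neither choice
changes the control-referenced interpretation. Timed tests carry a
`lower_better` flag so negative z always means worse performance.

A timepoint is impaired under the ICCTF-style rule when at least two
z-scores are −1.5 or lower, or any one is −2.0 or lower (both thresholds
inclusive). Longitudinally, impairment at baseline and 1 year is
*persistent*, impairment at 1 year only is *late-onset*, and both map to an
impaired outcome; a baseline-only deficit that resolves by 1 year falls
outside both categories and is labeled unimpaired (the two-case definition
is exhaustive), with a `resolved` flag for transparency. Missing scores at a
timepoint are ignored (classification uses the available scores and records
completeness); a fully missing timepoint is an error rather than a silent
guess.

Incidence is compared between groups with the uncorrected Pearson
chi-squared test on the 2×2 table (`correct = TRUE` adds the Yates
correction); the uncorrected statistic is the one consistent with the
incidence comparison this pipeline is built to reproduce.

## Connectome metrics

Weighted connectivity matrices are binarized to **minimum connection
density**: edges enter in descending absolute weight until no region is
fragmented from the rest. Equal-weight edges enter together (so an already
binary, connected matrix is its own binarization); when a fixed edge count
must be imposed — as in cohort-common mode — ties at the cutoff are broken by
(lower row, lower column). Negative weights are ranked by absolute value.
The default cohort mode applies the maximum of the subjects' minimum
densities to every subject, so the whole cohort is analysed at one density
with all networks connected; a per-subject mode retains each subject's own
minimum.

Nodal metrics are the standard binary-graph quantities: degree; clustering
coefficient `C_i = 2 t_i / (k_i (k_i − 1))` (ratio of observed to possible
edges among a region's neighbors, 0 when `k_i < 2`); unnormalized
shortest-path betweenness (reported magnitudes are path counts, not [0,1]
fractions); modularity via deterministic greedy agglomerative maximization
of Newman's `Q = Σ_s (e_ss − a_s²)`; and the participation coefficient
`P_i = 1 − Σ_s (k_is/k_i)²` of each region under that partition.

Hub status follows the 1-SD rule: a region is a hub when degree, betweenness
and/or clustering exceeds the across-region mean of that metric by more than
one SD; hubs with participation above 0.30 are connector hubs (bridging
modules), the rest provincial. For group-level hub tables, metrics are
computed per subject and averaged (which is why tabulated group degrees are
non-integer), while the partition and participation come from the group-mean
network — the mean adjacency binarized to its own minimum density.

## Prediction

Three feature sets are supported: six baseline patient/medical covariates
(age, education, ordinal cancer stage, minority status, menopausal status,
CAD distress total) for Model 1; those six plus three a-priori regions'
clustering for Model 2; and the six plus all regions' clustering (96 columns
at the default 90-region parcellation) for Model 3.

The evaluation protocol is strictly nested:

1. A stratified 75% training sample is drawn per outcome class. Fractional
   per-class test counts are rounded to the nearest integer with exact
   halves resolved by a fair coin, so a 17/14 cohort of 31 yields hold-outs
   of 7 or 8.
2. Recursive feature elimination runs entirely inside the training set: for
   each of 100 seeded inner partitions (75/25 stratified), features are
   ranked by Gini importance from a forest grown on the inner-train part and
   each candidate subset size is scored by predicting the inner-test part —
   every scored sample is outside the forest that predicts it. Subset sizes
   follow the full ladder `p, p−1, …, 1` for `p ≤ 20` and a halving ladder
   above (96, 48, 24, 12, 6, 3, 1), keeping the 96-feature model tractable.
   The size with the best mean accuracy wins, ties toward fewer features;
   the final features are the top-ranked of that size from a forest refit on
   the full training set.
3. A 500-tree forest with `mtry = floor(sqrt(p))` is retrained on the full
   training set with out-of-bag error estimation and applied once to the
   held-out 25%.

Forests are classical bagged CART ensembles (per-tree bootstrap of samples,
random feature subsets per split), fitted by ranger with a single thread and
an explicit seed; importances are mean decrease in Gini. Hold-out accuracy
gets a two-sided exact binomial p-value against chance 0.5 (minimum-
likelihood convention — the variant that doubles the one-sided tail at
p0 = 0.5); ROC AUC comes from the forest's vote fractions with midrank
handling of ties. AUCs of two models on the same held-out subjects are
compared by paired bootstrap: subjects are resampled 2000 times, and
`z = ΔAUC / SD_boot(ΔAUC)` with a two-sided normal p-value.

When held-out subjects never participate in RFE, training, *or* density
selection, the cohort-common binarization density inside `run_pipeline()` is
computed from training patients' minima only and then applied to everyone;
a held-out subject whose own minimum exceeds it would simply stay fragmented
at that density (metrics remain defined).

Random-forest regression supplements classification: one 500-tree regression
forest per cognitive test predicts the 1-year z-score from the selected
brain features, with fit summarised as adjusted R² from out-of-bag
predictions (`R² = 1 − MSE_oob/Var(y)`, then the usual `(n−1)/(n−p−1)`
adjustment) and a p-value from the implied F statistic — the natural mapping
when only R², n and p are in hand. Importance is the percent increase in
OOB MSE under per-feature permutation (the raw permutation increase scaled
by OOB MSE; the per-tree-SD-scaled variant some implementations print is not
used).

## The synthetic cohort generator

The generator's defaults are the study conditions the pipeline was designed
around: 31 patients vs 43 controls (90 regions, 5 modules), target
impairment incidence 0.55 in patients and 0.26 in controls, 41% of impaired
patients late-onset, a 3-SD cognitive effect on two tests, and a 0.5
fractional clustering deficit in five predictive regions (left lingual, left
calcarine, right insula, right middle temporal, right olfactory — one set of
anatomically plausible defaults, freely configurable).

**Connectivity.** Edge weights are Gaussian around a within-module mean
(0.60) or between-module mean (0.20) with SD 0.15, clipped to [−1, 1],
symmetric, zero diagonal. This is the simplest generative model with the
modular structure the modularity analysis assumes; the fidelity target is
downstream-statistic behavior, not fMRI realism. For impaired patients, the
edges among each predictive region's top-k strongest neighbors
(k ≈ 10% of possible neighbors, near the expected binarized degree) are
multiplied by `1 − clustering_effect`. Down-weighting the neighbor–neighbor
edges rather than the region's own edges lowers the region's clustering
coefficient while approximately preserving its degree, and because k is well
below the module size the collateral drop in module-mates' clustering stays
small — the planted regions remain the most discriminative columns.

**Cognition.** Raw scores are Gaussian around fixed per-test reference
means/SDs (arbitrary by construction: z-scoring against controls makes the
raw scales immaterial downstream). A planted-impaired subject has two
randomly chosen tests shifted down by the configured effect at the
timepoints its category dictates (persistent: all three timepoints;
late-onset: from post-chemotherapy on). Planted control deficits are capped
at 2 SD — control impairment is mild-to-moderate by definition, and the cap
keeps the control reference distribution close to Gaussian so that
sample-referenced z-scores behave like their population counterparts.

**Calibration.** The ICCTF rule applied to five independent Gaussian
z-scores trips at a base rate of about 0.125, and planting deficits in
controls inflates the control reference SD, which in turn pushes the
thresholds outward — the realized control rate is therefore a *non-monotone*
function of the control planting rate with a ceiling near 0.25. The
generator calibrates exactly under its own Gaussian model: the control
planting probability is the smallest value whose realized (self-referenced)
rate is closest to the target, and the patient planting probability then
follows in closed form from the resulting reference moments. A subject's
`true_outcome` is obtained by applying the ICCTF rule to its generated
scores against the *population* control reference, and the connectivity
deficit is planted per that outcome — so the planted brain signal is tied to
the label the downstream classifier recovers, up to the small borderline
noise introduced by estimating the reference from a finite control sample
(about 5% of subjects at the default sizes).

**Covariates.** Age uniform on 34–65 years, education in years, cancer stage
at the 16/65/19% I/II/III mixture, minority and menopausal binaries, and a
continuous CAD total; by default all are independent of outcome, and named
log-odds weights can tie any of them to the planting probability.

**Determinism.** A single master seed expands into keyed per-subject,
per-stage substreams, so the same configuration and seed reproduce the
cohort byte for byte and growing the cohort never reshuffles existing
subjects. Three cognition timepoints are always generated; connectivity
matrices default to baseline only, since prediction consumes pre-treatment
imaging exclusively.

**What the generator does not emulate.** No BOLD time series, motion or
scanner noise (generation starts at the connectivity-matrix level); no
spatial autocorrelation beyond the block structure; no test practice
effects or score discreteness; control impairment saturates near 0.25
rather than reaching 0.26 (see Calibration). The block-Gaussian networks
are *more* modular than real connectomes — few between-module edges survive
minimum-density thresholding, so group-level hubs in synthetic cohorts
type mostly provincial; the connector/provincial taxonomy is therefore
exercised on engineered networks in the tests rather than on generator
output. Passing tests on this generator demonstrate that the pipeline
recovers the statistical structure it assumes — not that real fMRI cohorts
satisfy those assumptions.

## Orchestration and reproducibility

`run_pipeline()` chains simulate (or load) → impairment scoring →
descriptive metrics and hub characterization → per-model prediction → AUC
comparison → regression, writing each stage's tables and a consolidated JSON
report. Every stage records an input-hash manifest; re-running with
unchanged inputs replays outputs instead of recomputing, and deleting a
late-stage output re-runs only that stage. Reports contain no timestamps, so
a fixed configuration and seed reproduce the report byte for byte. All
stochastic stages (split, inner partitions, forests, bootstrap) draw their
seeds deterministically from the single pipeline seed. The pipeline's
conceptual subcommands (simulate / metrics / impair / predict / compare)
correspond 1:1 to the exported functions; there is no shell wrapper because
the package is used as an analysis library.

## Numerical choices and edge cases

- Zero weights never count as candidate edges; a matrix whose nonzero edges
  cannot connect all regions is a hard error.
- Degenerate degrees: `C_i = 0` for `k_i < 2`; `P_i = 0` for isolated
  regions; a zero-variance metric can mark no hubs.
- Chi-squared incidence testing errors on empty impairment margins rather
  than returning 0/0.
- The bootstrap AUC comparison resamples until both classes appear in a
  resample; identical score vectors give `z = 0, p = 1` by convention.
- Adjusted R² requires `n − p − 1 > 0`; constant regression targets and
  constant classification outcomes are errors, not warnings.

## Problem sizes used in the checks

The packaged checks run the full pipeline on cohorts of 120 patients and 43
controls over ten seeds for both the planted-effect and the null condition —
large enough for stable hold-out statistics (test sets of ~30) while keeping
a complete run of the nested 100-partition RFE in the tens of seconds.
Smaller widths (24–30 regions, reduced partition counts) are used in unit
tests where the property under test does not depend on scale.
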