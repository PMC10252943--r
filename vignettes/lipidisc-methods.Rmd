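---
title: "Methods: two-class chemometric discrimination of lipid feature tables"
author: "lipidisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-class chemometric discrimination of lipid feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidisc)
```

# The problem and the data model

An untargeted lipidomics experiment on a treated/untreated food matrix
produces a table of chromatographic peak areas (arbitrary units; the
packaged catalog is on the AU × 10⁵ scale) for several hundred lipid
species over a small number of analytical runs. Here the motivating
system is Camembert cheese irradiated with X-rays at 3 kGy: 4 cheeses
per class, each analysed in triplicate, giving 12 non-irradiated (`NI`)
and 12 irradiated (`IRR`) runs over 479 species in 16 subclasses (345
triacylglycerols plus 42 oxidized forms dominate the positive ion mode;
phospholipids, ceramides and related classes make up the 79
negative-mode species).

`LipidFeatureTable` wraps this as a `SummarizedExperiment` (lipids as
rows, runs as columns) with the class label, cheese and replicate in
`colData` and the subclass/ion-mode/oxidation annotation in `rowData`.
All modelling functions consume the runs × lipids orientation through
`areaMatrix()` and the class coding `IRR` = +1, `NI` = −1 through
`classCoding()`.

Two working assumptions run through the whole stack:

* both classes are present and reasonably balanced (all resampling is
  stratified by class);
* areas are non-negative and complete — missing-value imputation is
  upstream of this package.

# Marker screening

`volcanoStats()` computes, per lipid, a two-group one-way ANOVA — with
two groups this *is* the squared pooled-variance t-test, so it is
implemented as the vectorised F = t² with p from the F(1, n−2)
distribution; a Welch option relaxes the equal-variance assumption —
and the log₂ fold change of class means. The screening threshold
p ≤ 0.05 is used as published, i.e. raw p-values; a
Benjamini–Hochberg-corrected screen can be emulated by the caller via
`p.adjust` on the returned column, but the reference procedure does not
correct and neither do we by default. A lipid with zero within-class
variance in both classes (possible in degenerate synthetic inputs)
receives p = 0 when the class means differ and p = 1 when they are
identical, with a message.

`selectPLSDAMarkers()` intersects the volcano rule with VIP ≥ 1 from a
PLS-DA fit on the full per-mode table. VIP uses the cumulative
explained-response weighting
VIP_j = √(p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a), whose mean square
is 1 — hence the conventional cut-off at 1.

# PLS-DA

`fitPLS()` is NIPALS PLS1 on the ±1 class coding: weights
w_a ∝ X_aᵀy_a, scores t_a = X_a w_a, with X and y deflated per
component. The response is centred; X is centred and, by default,
autoscaled. Autoscaling is a deliberate default: the catalog spans
areas from ≈1.5 to ≈1280 AU × 10⁵, and covariance-scale PLS would be
dominated by the triacylglycerol block; `autoscale = FALSE` preserves
centre-only behaviour. Columns with zero training variance are dropped
and recorded on the model. A component whose weight norm falls below
1e−12 stops the extraction (the residual carries no predictive
variation); prediction at the full rank equals ordinary least squares,
which the tests use as an oracle.

Hard classification thresholds the continuous prediction at 0; a
prediction of exactly 0 (a measure-zero event) goes to `NI` so the rule
is deterministic.

# Diagnostics

All scalar diagnostics live in one place (`diagnosticSet()`):

* Q² = 1 − PRESS/TSS on validation predictions.
* DQ² replaces PRESS by PRESS_D, which sums squared residuals only for
  class −1 runs with ŷ > −1 and class +1 runs with ŷ < +1. A prediction
  beyond its class target is perfect discrimination and contributes
  nothing, so DQ² ≥ Q² term by term. (The source description of the two
  summation conditions carries an evident typesetting slip — both
  printed as ŷ < −1; the implemented form is the one its own prose
  example, ŷ = 1.3 for y = 1 being perfect, requires.)
* Sensitivity = TP/(TP+FN) with `IRR` positive, specificity = TN/(TN+FP),
  accuracy, NMC = FN+FP.
* AUROC in the Mann–Whitney form (fraction of (IRR, NI) prediction
  pairs correctly ordered, ties at 0.5), computed from ranks on the
  continuous predictions.
* RMSECV = √(PRESS/n) — the standard definition, since none is printed.
* tRMSECV = ((max−x)/(max−min)) · (min/x), a monotone rescaling of
  RMSECV onto [0, 1]. The min/max are taken over the #LV scan within
  the current inner cross-validation loop — the only context in which
  a minimum and maximum coexist; with a degenerate range (max = min,
  or x at the minimum, including 0) the value is 1.
* I_eff is the plain sum of the seven statistics above (maximum 7,
  unbounded below). Outside a #LV scan tRMSECV has no defining range,
  so repetition-level `DiagnosticSet`s report it (and I_eff) as `NA`.

# Validation protocols

**Double cross-validation** (`doubleCrossValidation()`): per
repetition, stratified outer folds; within each outer training
portion, stratified inner folds evaluate every #LV in 1..`maxLV` on
the pooled inner-validation predictions, and the #LV maximising I_eff
(ties to the fewest components) is refit on the outer training portion
and scored on the outer test fold. Repetition-level diagnostics come
from the pooled outer-test predictions; the modal selected #LV is the
protocol's choice. Fold counts are not dictated by the reference
procedure; the defaults (outer 4, inner 5) give outer test folds of 6
runs and inner folds of 3–4 at the study's n = 24, keeping every
training portion class-balanced. `maxLV` defaults to 10, comfortably
above the optima of 8 (negative mode) and 5 (positive mode) reported
for the real data. If a training portion's rank cannot support the
scan, the scan truncates and the last supported component's
predictions extend the grid.

**Bootstrap** (`bootstrapValidation()`): n-out-of-n resampling with
replacement; out-of-bag runs validate. A training draw missing a class
(or an empty OOB set) is redrawn, fatal after 1000 consecutive
failures. An OOB set can legitimately contain a single class
(probability ≈ 0.4% per iteration at n = 24); the class-conditional
statistics undefined there are `NA` for that iteration and the
averages use the defined iterations only.

**Stratified random subsampling** (`subsamplingValidation()`): 3:1
train/validation within each class, re-drawn each iteration.

**Kennard–Stone** (`kennardStoneSplit()`): deterministic max-min
selection on autoscaled areas — seed with the two mutually farthest
runs, then add the run maximising its minimum Euclidean distance to
the selected set. Distance ties break to the lowest run index, and the
seed pair to the lexicographically smallest index pair, so repeated
calls agree exactly. The stratified variant runs the procedure within
each class with the training budget apportioned to class sizes. The
3:1 ratio of the single-split validation mirrors the subsampling
protocol.

**LDA branch** (`prepareLDAVariables()`, `fitLDA()`,
`crossvalidateLDA()`): volcano-selected lipids, ranked by ascending
p-value, capped at the per-class object count (LDA needs no more
variables than objects per category; the cap rule and ranking are the
package's resolution of an unstated tie rule). Normality per lipid and
per class is tested with the Lilliefors test at α = 0.05 via
`nortest::lillie.test` (the standard Dallal–Wilkinson small-sample
approximation, adequate at n = 12); lipids failing in either class are
natural-log transformed. The LDA itself is pooled-covariance with
equal priors — the design is balanced, so empirical priors would be
identical anyway — and a relative ridge of 1e−8 · trace(S)/p on a
near-singular pooled covariance; `ridge = 0` turns collinearity into
an error instead. The repeated CV uses the same stratified 3:1 split
as the subsampling protocol (the reference ratio for this branch is
unprinted). Only class-based statistics (sensitivity, specificity,
accuracy, AUROC, NMC) are reported for LDA: the discriminant score is
not on the ±1 coding scale, so Q²/DQ²/RMSECV are not meaningful there.

**Permutation test** (`permutationTest()`): N random relabellings;
each is evaluated by simple stratified k-fold CV (default 6-fold;
`folds = n` gives leave-one-out) at a fixed #LV, yielding NMC_P; then
p = (1 + #(NMC_P ≤ NMC))/N with floor 1/N. The reference NMC is the
rounded mean NMC over the double-CV repetitions (a single-run NMC
would be noisier; the rounded average is the stabler resolution of an
unstated choice). For balanced classes the H0 distribution is centred
near n/2, the binomial(n, ½) mean — a property the tests assert with a
±1.5 tolerance rather than an exact target.

Replicates of the same cheese are assigned to folds independently in
every protocol, matching the run-level treatment of the reference
analysis; leakage-aware grouping by cheese can be emulated by
aggregating replicates upstream.

# PCA exploration and outlier screening

`pcaFit()` runs SVD-based PCA on autoscaled areas, with each
component's sign fixed so its largest-magnitude loading is positive.
For a chosen component count (default 2, the pair inspected in score
plots) it computes per-run orthogonal distances (residual sum of
squares off the score plane) and Hotelling T² distances (Mahalanobis
in score space), each normalised by its mean so the training average
is 1. `outlierScreen()` flags runs exceeding moment-matched scaled
chi-squared critical limits at significance α (default 0.01): a
distance with mean m and variance v is treated as (m/h)·χ²_h with
h = 2m²/v. Each run is judged against moments of the *other* runs
(leave-one-out), because with classical moments a single gross outlier
inflates its own limit and masks itself at these sample sizes. The
exact limit convention of the reference analysis is unstated; this is
the standard convention of the chemometric SIMCA family plus the
single-outlier robustification.

# The synthetic-data generator

`generateDataset()` emulates the study conditions from two packaged
fixtures: the 42-marker catalog (per-class means ± SDs, model tags)
and the 479-species subclass census. Defaults are the study design —
4 cheeses × 3 replicates per class — and are not tuned per analysis:

* Marker species draw from their printed per-class mean/SD; non-marker
  species have no class effect, with a per-species mean sampled
  log-uniformly between 10 and 1000 AU × 10⁵ (the magnitude range of
  the non-oxidized catalog entries; exact values are unidentifiable
  from printed summaries) and CV 0.25, a typical replicate-level
  spread for peak areas.
* `cheeseEffectSdFrac` (default 0.3) routes that fraction of each
  species' *variance* into a cheese-level random effect shared by the
  three replicates, leaving the total SD equal to the printed value.
  The reference statistics treat the 12 runs per class as i.i.d., so
  the decomposition is an extension for probing pseudo-replication:
  with a shared cheese effect, chance class-specific offsets persist
  across CV folds and lift apparent null accuracy — the package's
  chance-level checks therefore set the fraction to 0. Reproduction
  runs also use 0, matching the i.i.d. treatment.
* The default distribution is a truncated normal (floor 1e−3
  AU × 10⁵, redrawing sub-floor values up to 100 times before
  clamping), because the catalog reports arithmetic means ± SDs; a
  moment-matched lognormal is available for skew-sensitivity checks.
* `generateNullDataset()` replaces each marker's class parameters by
  the pooled mean (mean_NI + mean_IRR)/2 and pooled SD
  √((sd²_NI + sd²_IRR)/2), removing every class effect.

What the generator does *not* emulate: retention time, m/z, adducts,
isotopes, missing values, batch or injection-order drift, and any
between-species correlation beyond the cheese effect (real lipid
abundances co-vary strongly within subclasses). Tests passing on this
surface therefore validate the *procedures* — their formulas,
invariances and null behaviour — not the instrument-level realism of
the data.

# Numerical choices and degenerate inputs

* Ties at the classification threshold go to `NI`; Kennard–Stone ties
  go to the lowest run index; #LV ties go to the fewest components.
* Zero-variance lipids: dropped (with a record) by PLS and PCA;
  exact-equality p-value rule in the volcano screen.
* Score orthogonality and VIP normalisation hold to ≈1e−8 relative
  tolerance and are asserted as such in the tests.
* All protocol RNG flows from explicit integer seeds; the pipeline
  derives per-stage seeds from one master seed by fixed offsets and
  stores them in its report bundle.

# Problem sizes used by the checks

The packaged checks run double CV at 100–200 repetitions, the LDA CV
at 2,000–10,000 repetitions, and the permutation machinery at
60–500 permutations — sizes chosen so the Monte-Carlo error of each
asserted quantity is well inside its assertion band while the whole
suite stays interactive. The protocol defaults (200 / 10,000 / 30,000)
match the reference analysis and are what `runPipeline()` uses.

# Known limitations

* Two classes only; no multi-class generalisation of DQ², I_eff or the
  selection rules.
* The real study's acquisition-level results (its PCA variance
  percentages, per-repetition dispersions, the exact 40/24 marker
  identities) depend on the undeposited raw data and are not
  reproduction targets; the package reproduces the procedures and the
  printed summary statistics they imply on catalog-parameterised
  synthetic data.
* The LDA branch with 12 variables and 9 training runs per class sits
  at the edge of covariance estimability by design fidelity; the ridge
  keeps it defined, but its specificity is noticeably more variable
  than PLS-DA's on the same tables (visible in `runPipeline()`
  bundles).
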