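---
title: "Methods: the double-loop retention model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the double-loop retention model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retnet)
```

This vignette documents the model implemented by `retnet`, the design
choices that were genuinely open, the synthetic-data generator that
stands in for clinical measurements, and the limits of what the test
suite demonstrates.

## 1. The retention statistic

Retention of a metal in the body cannot be measured directly; it is
inferred from how fast the metal clears from blood plasma. The package
computes, per subject and metal,

1. a body-surface correction `BS` (Mosteller form). The canonical
   grouping of the correction is ambiguous in practice, so both readings
   are provided: `body_surface(w, h, "printed")` returns
   `1.73 * sqrt(w*h/3600)` (the default) and `"mosteller_ratio"` returns
   `sqrt(w*h/3600) / 1.73`, the conventional clinical normalisation of a
   clearance to 1.73 m². The two differ by the constant factor 1.73²;
   because retention is invariant to rescaling the whole clearance
   series (σ rescales identically), the choice does not affect retention
   when applied uniformly to a cohort.
2. the Reberg clearance `CL = c_urine * D / (c_blood * 1440 * BS)`,
   with 1440 a named minutes-per-day constant;
3. the retention `exp(-CL² / (2σ²))`, where σ is the standard deviation
   of the cohort's clearance series for that metal. The population
   (n-denominator) standard deviation is the default, the sample (n−1)
   form selectable; with only "the standard deviation of the data
   series" to go on, the population form was chosen as the natural
   descriptive statistic of a complete series. The transform is a
   Gaussian kernel: zero clearance gives retention exactly 1, and
   retention is strictly decreasing in clearance, so retention ranks are
   exactly the reverse of clearance ranks.

If a cohort table carries a `body_area_m2` column it is used as given;
otherwise it can be derived from weight and height. Degenerate inputs
fail loudly: zero blood concentration (clearance unmeasurable), σ ≤ 0
(constant clearance series), non-positive physiology.

## 2. Preprocessing

* **Gross errors.** A one-pass k·σ rule (default k = 3) around the mean
  retains indices within the band. One pass is deliberate — iterating
  the rule changes the band after each removal and has no principled
  stopping rule. Note a small-sample property: for n values the largest
  attainable |z| is (n−1)/√n, so at n ≤ 9 a 3σ rule can never reject
  anything; the filter is a cohort-scale tool.
* **Normalisation.** The network pipeline uses only the affine map to
  [−1, 1], fitted on the training split and applied to the test split,
  so no test information leaks into the scaling. Values outside the
  fitted range extrapolate beyond [−1, 1]; clipping exists but is off by
  default, because silently clamping out-of-range exposures would hide
  exactly the cases a user should see. Z-score standardisation is
  implemented (population sd) and can be switched on ahead of the range
  map (`zscore = TRUE`); it belongs to data cleaning and QC rather than
  to the network contract, hence the default off. Both transforms store
  their parameters and invert to the identity within 1e−12.
* **Targets.** Retention is already in (0;1); it is additionally mapped
  to [−1, 1] for training (errors are defined on the normalised scale)
  and inverse-mapped for reporting.
* **Splits.** The 80/20 split is seeded uniform sampling without
  replacement — the seed is mandatory, so a split is always
  reproducible. Cross-validation uses contiguous test windows
  `[floor(j·n/k), floor((j+1)·n/k))` shifted sequentially from the first
  element; floor-based boundaries partition any n ≥ k (for n = 242,
  k = 5 the windows are 48/48/49/48/49).

## 3. The MLP blocks and RPROP

Each block is a from-scratch single-hidden-layer perceptron: 5 hidden
neurons with `tanh(0.7x)` activation (0.7 is an input-slope "curvature"
multiplier), a linear output neuron, weights initialised uniformly on
[−0.5, 0.5] under a seed, biases zero. The activation registry also
provides sigmoid, linear, ReLU, threshold and SeLU with analytic
derivatives; gradients are exact backpropagation of the mean squared
error (no ½ factor, matching the error definition used for reporting)
and are verified against central finite differences in the tests.

Training is full-batch RPROP in the variant without weight backtracking:
each weight carries its own step size Δ, grown by η⁺ = 1.2 when the
gradient keeps its sign, shrunk by η⁻ = 0.5 on a sign flip with the
direction update skipped once (stored gradient zeroed). Δ starts at 0.5
and is clamped to [1e−6, 50] — classic bounds for this algorithm. The
mapping of the method's named constants is: "descent step" → η⁻,
"split factor" → η⁺, and the separately quoted learning rate 0.5 → the
initial step Δ₀; all are exposed in `rprop_config()`. Full-batch
gradients are required by the sign logic — per-example updates would
make the sign of the previous gradient meaningless.

RPROP does not descend monotonically, so `mlp_train()` records the full
per-epoch error history, returns the best-so-far weights, and reports
`best_epoch` and `final_loss` so the retention of non-final weights is
auditable. Default training length is 10,000 epochs; a 7-5-1 block on
~200 rows trains in roughly two seconds, so the default is used
throughout the acceptance checks, while the unit tests use a few hundred
epochs where convergence quality is not the property being tested.

## 4. The double loop

`double_loop()` assembles, per metal, the long-term dataset (7 features:
weight, height, body area, age, sex, water, soil) and the short-term
dataset (the same minus soil), trains each block on its own 80/20 split
of its own dataset, and only then builds the closed loop: confidence
coefficients from the two aggregate test errors, and fused predictions
as the convex combination of the block outputs on the retention scale
(after inverse normalisation, since the fusion is stated in retention
terms).

The confidence scheme is **error-proportional exactly as published**:
`a_l = Err_T(l) / (Err_T(l) + Err_T(s))`, which assigns the larger
weight to the block with the *larger* test error. The published
worked-example table confirms this reading of the formula (e.g. zinc:
0.0073/(0.0073+0.0351) = 0.172, matching the printed 0.1718), so the
implementation follows it verbatim; the conventional inverse-error
scheme is available via `inverse_error_weights = TRUE` for comparison
and is off by default. Copper's printed row is internally inconsistent
at four decimals between the two published error tables, so exact checks
use zinc, chrome and lead only.

Per-metal models are fully independent — no parameter sharing. The
fitted object answers `print`, `summary`, `coef`, `predict`, `fitted`,
`residuals` and `plot` (reference vs fused retention, subjects ordered
by reference value). `cross_validate()` re-initialises weights per fold
("small random values"), marks degenerate folds failed without aborting
the rest, and reports per-fold block errors (normalised scale) and fused
errors (retention scale) with a mean ± sd summary.

## 5. The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the method
assumes, with planted ground truth:

* **Demographics.** Default 242 subjects with the study's sex ratio
  (54 boys), mean ages 11.7 (boys) / 10.4 (girls), spread 2.2 years,
  ages rounded to whole years in 5..17; height, BMI-derived weight and
  Mosteller body area are age-consistent; diuresis ~N(1400, 250) mL
  clamped to a physiological range.
* **Exposures.** Water (mg/L) and soil (mg/kg) concentrations are
  log-normal with per-metal medians in realistic urban background
  ranges and a common log-scale spread of 0.45.
* **Planted mapping.** A latent index combines standardised log-water
  (0.85), log-soil (0.08), age (−0.30), sex (−0.20) and body size
  (0.35); the index is standardised and passed through a logistic of
  slope 3 with a 4% clearance floor, scaled to 5 mL/min. Higher exposure
  → lower clearance → higher retention, monotonically. Soil enters only
  the long-term component; water affects both blocks, mirroring the
  long- vs short-term exposure semantics. The slope and floor were
  calibrated once so that planted retention spans roughly (0.02, 0.99)
  over a default cohort — the Gaussian-kernel geometry ties the lower
  end of the span to max(CL)/sd(CL), which cannot be pushed to 0.05
  without sacrificing the upper end for a unimodal clearance
  distribution — and so that both blocks are learnable to a test error
  well under 0.05 at the default observation noise.
* **Back-solving.** Blood concentrations are log-normal; urine is solved
  from the planted clearance through the Reberg formula, so running the
  retention pipeline on the generated biosubstrate columns recovers the
  planted clearance to machine precision (a construction identity the
  tests assert at noise 0).
* **Noise and missingness.** The observed retention target is the
  planted retention plus Gaussian noise (default sd 0.02, the level at
  which block recovery is tested; configurations with sd ≥ 0.5 are
  refused as infeasible), clipped into (0;1). An optional missingness
  rate blanks per-metal exposure fields, emulating the per-metal dataset
  attrition implied by cohort tables of varying size; the default is 0
  since the true attrition mechanism is unknown.

What the generator does **not** emulate: real geochemical correlation
between metals and media, assay detection limits and censoring,
non-Gaussian measurement error, or any genuine physiology of metal
kinetics. Passing parameter-recovery tests therefore shows the pipeline
is correct and trainable under the model's own assumptions — not that
the published accuracies transfer to real cohorts, which remain
unverifiable without the private clinical data.

## 6. Numerical choices and degenerate inputs

* Tolerances: normalisation round-trips at 1e−12; gradient checks at
  1e−6 relative against central differences (h = 1e−6); fusion weight
  sums validated at 1e−9.
* Gross-error filtering of exposure columns is wired into
  `double_loop()`/`cross_validate()` behind `gross_filter` (default
  off, matching the bare model contract). The recovery tests enable it,
  as data cleaning precedes training in the intended pipeline; without
  it, a single far-tail log-normal exposure draw landing in a test fold
  extrapolates outside the fitted [−1, 1] range and can dominate a
  40-row mean error.
* Block outputs outside (0;1) on the retention scale are reported with a
  warning (clipping optional) rather than silently clamped.
* A constant feature column refuses training (no [−1, 1] map exists); a
  constant clearance series refuses the retention transform (σ = 0);
  both blocks' test errors being exactly zero refuses weight computation
  (fusion undefined).
* Model JSON stores numbers at 17 significant digits, so a reloaded
  model predicts bit-identically.

## 7. Problem sizes used in the checks

The acceptance checks train 7-5-1/6-5-1 blocks for 10,000 epochs on
synthetic cohorts of n = 200 (about two seconds per block), across the
four metals and three seeds for parameter recovery and five seeds for
the closed-loop comparison; the published confidence-coefficient table
is reproduced from its printed inputs directly. These sizes match the
study scale (n = 242, 10,000 epochs) closely enough that no scaled-down
claim is involved.
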