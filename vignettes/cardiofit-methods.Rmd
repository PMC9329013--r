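---
title: "Methods: cascade curve fitting and a small neural network for heart-disease identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade curve fitting and a small neural network for heart-disease identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofit)
```

## The problem and the data model

The package identifies heart-disease patients from 13 routine clinical
features — age, sex, chest-pain type, resting blood pressure, serum
cholesterol, fasting blood sugar, resting ECG category, maximum heart
rate, exercise-induced angina, exercise ST depression, ST-segment slope,
fluoroscopy vessel count and a thalassemia code — plus a binary outcome
`Hd` (1 = disease). The feature order is fixed package-wide by a single
schema constant: the cascade fits features in that order and the network's
input-weight columns are indexed by it, so there is exactly one place
where "column 8 means maximum heart rate" is defined.

Before modelling, every feature is min–max standardized,
$y = (x - x_{\min})/(x_{\max} - x_{\min})$, using per-feature extrema
fitted on the training data and stored invertibly (`fit_normalization()`,
`normalize_heart()`, `denormalize_heart()`). Two policies were genuinely
open and are decided as follows:

* **Out-of-range inputs at prediction time** (a new patient older than any
  training patient): the transform is applied unclamped with a warning by
  default, because silently clamping hides a covariate-shift problem;
  `clamp = TRUE` is available when a bounded input is structurally
  required.
* **Missing values** are rejected by default; `drop_missing = TRUE` drops
  offending rows and reports the count. No imputation is offered — the
  models are closed-form and an imputation policy would dominate their
  behaviour silently.

## The residual curve-fitting cascade

Stage 1 regresses `Hd` on the first feature by ordinary least squares.
The stage's intercept is interpreted as a "constant" that in truth depends
on all remaining features, so the per-sample residual
$r_i \leftarrow r_i - a_k x_{ik}$ is carried forward as the target of the
next stage. After 13 stages the final intercept $M_0$ remains, giving the
additive correlation $\hat H_d = M_0 + \sum_k a_k x_k$. Three numerical
choices matter:

* **Per-stage fits are closed-form** (two-parameter normal equations,
  `fit_univariate()`): no iterative optimizer, so coefficients are exact,
  deterministic and unit-testable against a brute-force
  $\mathrm{cov}(r, x)/\mathrm{var}(x)$ oracle.
* **The residual "constants" are per-sample vectors.** Treating them as
  scalars would make stages 2–13 ill-defined; the vector reading is the
  minimal one under which each stage is an ordinary scatter fit.
* **$M_0$ is the 13th stage's OLS intercept.** Each stage's intercept
  equals $\bar r - a_k \bar x_k$, which the tests assert directly.

The cascade equals joint multivariate least squares **exactly** when the
feature columns are empirically uncorrelated (each stage's regressor is
orthogonal to all later ones), and is biased when they are correlated —
each stage absorbs part of its correlated partners' effects. Both facts
are asserted in the test suite, the first on designs built by
`make_orthogonal_features()` (QR-orthogonalized columns rescaled to
$[0,1]$; per-column affine maps preserve zero covariance), the second on a
constructed correlated pair. This is the honest statement of the method's
scope: it is a fast, fully inspectable approximation whose validity
degrades with feature correlation.

Classification uses a threshold of 0.5 on the continuous score — the
midpoint of the 0/1 coding — configurable everywhere it appears.

## The neural network

A 13-input, single-hidden-layer, single-output network: hidden activations
$\mathrm{tansig}(x) = 2/(1+e^{-2x}) - 1$ (identically $\tanh x$;
implemented from the defining form with the exponential branch chosen by
sign so neither branch can overflow), linear output. `published_ann()`
freezes the published 10-unit instance; its 130 input weights are stored
row-major as 10 rows × 13 schema-ordered columns, a convention isolated in
that one constructor so it can be flipped in a single place if evidence
ever demands it.

`train_ann()` fits the network from scratch:

* **Split**: seeded random permutation, then contiguous 90/5/5
  train/validation/test slices (sizes rounded to sum to $n$).
* **Initialization**: seeded uniform $(-0.5, 0.5)$ for all weights and
  biases.
* **Optimization**: full-batch gradient descent on the MSE with exact
  backpropagated gradients (verified against central finite differences at
  step $10^{-6}$ to relative error $<10^{-4}$). The step size is governed
  by a bold-driver rule — grow by 5% after an epoch that does not increase
  the training loss, halve and reject the step otherwise. This keeps the
  optimizer plain gradient descent while removing the need to hand-tune a
  learning rate per hidden size; a fixed step that is safe for $h = 25$ is
  needlessly slow for $h = 5$.
* **Early stopping**: training halts after `patience` epochs without a new
  validation-MSE minimum, and the best-validation weights are restored, so
  the returned validation MSE can never exceed any recorded epoch's value
  (asserted in the tests).
* **Hidden-size sweep**: every width in `hidden_sizes` (default 5–25) is
  trained with its own seeded initialization; the winner is the minimum
  validation MSE. With a 5% validation split of a ~300-row dataset the
  validation set holds about 15 rows, and a run whose early stopping froze
  essentially untrained weights can score well on 15 rows by luck; the
  sweep therefore excludes *degenerate* runs — those whose restored
  weights do not beat the constant-mean predictor on their own training
  rows — from model selection (falling back to all runs only if every run
  is degenerate). `sweep_report()` tabulates MSE, Pearson R and the
  degeneracy flag per size.

Determinism is a contract: the same `train_config()` (including `seed`)
gives bit-identical results, which the suite checks by serializing two
independent runs.

## Metrics

`evaluate_predictions()` reports MAE, MSE, RMSE, and *both* R² variants:
the coefficient of determination $1 - SS_{res}/SS_{tot}$ (the headline
metric) and the squared Pearson correlation, which regression GUIs often
display. They coincide exactly when predictions are affinely calibrated to
the outcomes and diverge under miscalibration; reporting both removes the
ambiguity about which is meant. For binary outcomes the thresholded
confusion counts and accuracy are added. Permutation importance
(`permutation_importance()`) is the explainability tool offered: seeded
within-column shuffling, metric degradation averaged over repeats. It is
plumbing, not a Shapley-value method, and is documented as such.

## The synthetic-data generator

`generate_heart_data()` emulates the clinical table so that every stage of
the pipeline can be tested against known ground truth:

* **Marginals**: continuous features are Beta distributions on $[0,1]$
  matched to a target mean and standard deviation, then mapped to raw
  clinical units over the schema's plausible ranges (age 29–77 years,
  blood pressure 94–200 mm Hg, cholesterol 126–564 mg/dl, heart rate
  71–202 bpm, ST depression 0–6.2); categorical features are exponentially
  tilted distributions over their coded domains solved to match a target
  normalized mean. The default targets (`table2_marginals()`) are taken as
  printed from the study conditions, including their oddities; where a
  printed standard deviation exceeds the variance bound $m(1-m)$ attainable
  on a bounded interval (the blood-pressure row), the generator caps the
  variance at 98% of the bound. Only two moments are matched — skewness
  and kurtosis are left free, a documented limitation.
* **Mechanism**: linear score with known 13-vector of coefficients
  (default: the published cascade slopes with intercept 0.6861), a
  logistic variant, or a fixed "teacher" network.
* **Noise and labels**: Gaussian score noise with `noise_sd = 0.35` by
  default — chosen once so the residual scale of the synthetic benchmark
  is comparable to the curve-fit residual scale reported for the original
  data (RMSE ≈ 0.37) — then threshold labelling at 0.5 (the default) or
  Bernoulli labelling with probability $\mathrm{logit}^{-1}(4(s-0.5))$, a
  sigmoid centred on the decision threshold.
* **Correlation knob**: a shared Gaussian latent factor feeding a Gaussian
  copula across features, `correlation` $\in [0,1)$.

What passing tests on this generator do **not** show: the synthetic table
reproduces marginal moments and a known mechanism, not the joint
distribution, measurement error or missingness of real clinical data, so
recovery results here certify the *algorithms*, not clinical performance.

## Problem sizes and numerical tolerances

The suite exercises: exact identities on the frozen published constants;
normalization round-trips at $10^{-10}$; noise-free cascade recovery on
orthogonal designs of 150–300 rows at $10^{-8}$ against a joint-OLS
oracle; per-stage brute-force slope oracles at $10^{-10}$; the forward
pass against a loop-based oracle at $10^{-12}$ over 100 random inputs;
gradient checks at relative error $10^{-4}$; and teacher–student
behavioural recovery (5000 noise-free training samples from a 3-unit
teacher, held-out coefficient of determination > 0.95 for a 6-unit
student). The benchmark used by `scripts/acceptance.R` is the default
303-patient spec with the full 5–25 hidden-size sweep.

## Known limitations

* The cascade's coefficients are order-dependent; the package fixes the
  derivation order rather than searching over orderings.
* No standard errors or tests accompany the cascade slopes — the method
  is a deterministic decomposition, not an inferential model.
* Training is full-batch on CPU; it is sized for hundreds-to-thousands of
  rows, not for large-scale data.
* The published weight matrices are transcribed at the printed two-decimal
  precision; scores computed from them inherit that rounding.
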