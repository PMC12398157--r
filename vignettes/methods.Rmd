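---
title: "Methods: postpartum cardiovascular risk models on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postpartum cardiovascular risk models on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ppcvd` reproduces, at desk scale, the workflow used to ask whether
pregnancy and reproductive history improves 10-year cardiovascular risk
prediction in women who have been pregnant: external validation of a
QRISK-style benchmark equation, recalibration of its baseline risk, and
development plus internal validation of updated Cox models. The primary-care
cohort such studies are run on is not distributable, so the package's first
module is a synthetic cohort generator whose defaults encode the published
cohort's statistical structure; everything downstream is exercised and
tested against it.

## The synthetic world

`default_simulation_spec()` states the world once:

* **Predictors.** Binary conditions and pregnancy/reproductive factors at
  their published prevalences (e.g. pre-eclampsia 3.3%, migraine 9.0%,
  miscarriage 22.4%, PCOS 3.8%); age, SBP and BMI as truncated normals with
  the published means and SDs (32.01 (6.63) years, 115.16 (12.72) mmHg,
  25.68 (5.71) kg/m²); the lipid ratio and SBP variability as log-normals
  matched to their published medians and IQRs; ethnicity (5 CPRD-style
  categories) and smoking (non/ex/current) at the published proportions —
  the sub-1-in-10,000 moderate/heavy smoker categories are collapsed into
  "current", which is the contrast the hazard-ratio table reports; gravidity
  from the published category distribution with the open "5 or more" class
  spread over 5–10 with geometrically decaying weights; Townsend deprivation
  as equal quintiles 1–5 (median 3, as published). Truncated-normal parent
  parameters are moment-matched so the *realized* truncated moments equal
  the stated ones — otherwise truncation to 15–49 would shrink the age SD by
  ~4% and the marginal-recovery tests would rightly fail.
* **Independence.** Predictors are drawn independently: only marginals are
  published, and inventing a correlation structure would manufacture
  unfalsifiable joint behaviour. This is the generator's main departure from
  real data, where risk factors cluster; consequences are discussed under
  "what a green test establishes".
* **Event model.** The true log-hazards are the logs of the published
  full-model (established + pregnancy predictors) hazard ratios, applied on
  the same fractional-polynomial scales the models use (age/10, BMI/10,
  (SBP/100)²). Event times are exponential over this proportional-hazards
  structure. The baseline rate is calibrated at generation time so the
  marginal 10-year cumulative incidence hits a configurable target, default
  1% — the source reports 0.98% events ever and 0.38% within 10 years
  without reconciling them, so the target is a stated parameter rather than
  a derived fact.
* **Censoring.** Uniform administrative censoring on 1–10 years plus
  exponential dropout at 0.094/year, the rate solving
  P(min(censor) > 3.66) = 1/2 given the admin window, so the default
  median follow-up brackets the published 3.66 years (tests require
  [3, 4.5]).
* **Missingness.** Missing-completely-at-random at the published
  proportions (SBP 16%, its SD 40%, BMI 24%, lipid ratio 91%, smoking 18%,
  Townsend 0.11%). Real EHR missingness is informative; MCAR is the only
  mechanism the published marginal rates identify.
* **Imputation policy.** Continuous measurements are singly imputed with
  the mean of observed values in the subject's 5-year age band (the source
  says "based on age and sex" without stating bands; all subjects here are
  female, and 5-year bands are common QRISK-adjacent practice — the width is
  an argument); smoking defaults to non-smoker, ethnicity to white,
  deprivation to the cohort median, and absent condition flags mean
  absence. Candidate predictors at or above 40% missing are excluded from
  development.
* **Seeding.** One root seed feeds named substreams per operation, so
  toggling missingness cannot perturb event-time draws and every output is
  a pure function of (spec, seed).

## Model development choices

* **Cox fitting** uses the Efron tie correction (year-resolution synthetic
  times produce heavy ties), Newton iterations to 1e-9 relative
  log-likelihood, 100 iterations max. Constant design columns (a rare
  condition with no carriers in a small resample) are dropped with a
  warning rather than failing a bootstrap replicate.
* **Centering.** The linear predictor is centered at its fit-time mean and
  the constant stored in the model, making the Breslow baseline and the
  predicted risks invariant to covariate location shifts.
* **Breslow baseline.** Implemented from its definition (event-count over
  risk-set sum of exp(centered LP)); the in-sample identity mean(predicted
  risk) ≈ KM risk is a test.
* **FP selection** uses the standard power grid {-2, -1, -0.5, 0, 0.5, 1,
  2, 3} and the closed test FP2 vs null (4 df), vs linear (3 df), vs FP1
  (2 df) at α = 0.05. FP forms are fixed *before* LASSO, matching the
  source's sequencing, and the bootstrap does not re-select them by default
  (a flag inverts this; the source is silent).
* **LASSO** penalizes only the candidate terms (penalty factor 0 on forced
  QRISK-style predictors), chooses λ by 10-fold cross-validated partial
  likelihood at the minimum (the source names no rule; λ-rule and folds are
  arguments), and the reported model is always an unpenalized refit on
  forced + selected terms — shrunken coefficients never leave the selection
  routine.
* **Recalibration** fits the benchmark linear predictor as a Cox offset
  with no free coefficients and replaces only the baseline survival;
  coefficients and centering are untouched.

## Validation choices

* **Pseudo-values** are the exact jackknife of the KM cumulative incidence,
  computed in O(n log n) by sharing two cumulative sums of log KM factors
  across all leave-one-out curves (the naive jackknife is O(n²) and
  infeasible at n = 200,000); exact agreement with the naive jackknife is
  tested on small censored fixtures, and mean(PV) equals the full-sample KM
  incidence to 1e-10.
* **Calibration regression** uses quasi-likelihood estimating equations
  with a cloglog link and constant working variance (pseudo-values fall
  outside [0, 1], ruling out binomial families) and robust sandwich
  standard errors, computed in-package. Predicted risks are clamped to
  [1e-10, 1 - 1e-10] before the cloglog transform to guard S0 = 1 edge
  cases. Sign convention: negative intercept means predictions are too
  high.
* **Time-dependent C** is Uno's IPCW truncated concordance (censoring
  weights from the KM of the censoring distribution); the source names the
  measure but not the estimator, and this is the standard horizon-anchored
  choice.
* **Royston's D** maps LP ranks to Blom normal scores, divides by
  κ = sqrt(8/π), and takes the Cox coefficient; R²_D follows from the
  closed-form identity, which is tested exactly.
* **Confidence intervals**: infinitesimal-jackknife SE for both
  concordances, model-based for D, log-scale delta method (Greenwood SE)
  for O/E — the source reports CIs without naming methods.
* **Net benefit** uses the KM-among-positives construction for survival
  data, thresholds default to a 0.01-step grid, and treat-none is
  identically zero.
* **Bootstrap optimism** reruns the full recipe — including selection —
  inside every replicate; a regression test asserts selected sets differ
  across replicates when candidates are pure noise. Optimism is reported
  for C, D and the calibration slope (the source adjusts C only; the others
  are labelled by-products). Failed replicates are skipped and counted, not
  retried.

## Degenerate inputs and numerical guards

Fractional polynomials requiring logs or non-integer powers raise a domain
error naming the variable (in particular, a benchmark LP at or below -4
makes the (LP+4)³ terms undefined; the engine refuses rather than clamps).
A constant LP yields D = 0 with a warning; zero-event groups report
undefined subgroup metrics rather than erroring; a horizon materially past
the last observed time returns the last baseline value with a warning.
The ≥ 40% missingness exclusion uses "at or above", which reproduces the
published exclusion of a predictor reported at a rounded 40%.

## What a green test does and does not establish

The generator recovers published *marginals*, hazard ratios and follow-up;
it does not emulate predictor correlation, informative missingness,
practice-level clustering, or pregnancy-episode timing (index date is
simply time zero). Tests therefore establish that the estimators are
correct and the pipeline faithful — parameter recovery within Monte-Carlo
error, exact analytic identities, oracle equivalence on small fixtures —
not that the published headline performance (C ≈ 0.70-0.73 in the real
cohort) is reproduced: absolute discrimination depends on the joint
predictor distribution, which the synthetic world deliberately does not
claim to know. In-sample calibration checks (O/E ≈ 1, slope ≈ 1 at
n = 200,000, ~2,000 events) carry the sampling noise that event count
implies — the slope's sampling SD is ~0.04, comparable to the published
slope CI half-width of 0.05 at a similar event count.

## Deliberately out of scope

Real-data access and clinical code lists; multiple imputation with pooling
(the single-imputation policy and a complete-case flag mirror the primary
and sensitivity analyses); competing risks; time-varying effects;
practice-level random effects. The per-module command-line wrappers a
data-extraction tool would carry are not shipped: this is an analysis
package in the survival-modelling tradition, and its interface is its
functions (`run_study()` orchestrates the whole graph).
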