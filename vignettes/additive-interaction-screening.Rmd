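---
title: "Screening drug pairs for additive-scale synergy on abnormal ALT elevation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug pairs for additive-scale synergy on abnormal ALT elevation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altsynergy)
```

## The problem

Drug-induced liver injury usually announces itself as an abnormal rise of
serum alanine aminotransferase (ALT). Individual hepatotoxic drugs are
reasonably well catalogued; what is much harder to see in spontaneous
reports is whether two drugs taken together raise the risk *more than the
sum of their individual effects*. `altsynergy` implements an end-to-end
screen for such synergistic pairs in longitudinal electronic health
records: cohort construction anchored on repeated liver-function tests,
binary exposure features with pairwise product terms, penalized logistic
regression, and an additive-scale interaction measure with bootstrap
confidence intervals.

Because the clinical data this kind of analysis runs on cannot be shipped,
the package contains a synthetic EHR generator with *planted* effects.
Every statistical guarantee quoted below is a property the test suite
actually measures on that generator.

## Outcome and cohort definition

A patient qualifies when they have ALT measured on at least three days
within some 90-day span (inclusive day arithmetic, `last - first <= 90`)
and the first two values sit inside the normal range of 4.0--44.0 U/L.
The latest measurement day of the span is the **index date**, the anchor
for both outcome and exposure:

* **case** — index-date ALT strictly above 132.0 U/L (3&times; the upper
  limit of normal);
* **control** — ALT within 4.0--44.0 U/L on *every* measurement day of
  the span, index date included;
* **excluded** — everything else: index ALT in (44, 132] (mild elevations
  are confounded by metabolic disease), any ALT below 4.0 U/L, patients
  under 18, a liver panel (ALT/AST/TBL/ALP) missing on *both* the first
  measurement day and the index date, pre-existing liver-disease
  diagnoses, or any hepatoprotectant prescription at or before the index
  date.

Two readings of the measurement-frequency rule are defensible: a window
anchored at the first test ever, or a rolling window. We use the rolling
reading and take the *earliest* qualifying span, which is deterministic;
the first and second days are the two earliest days of that span. With
more than three tests in the span, "second" means the second-earliest
day. Below-range ALT gets its own exclusion reason (`below_range_alt`)
rather than being silently folded into the intermediate band: a value
under 4.0 U/L is neither a case nor "within the normal range".

Exclusions are applied in a fixed order (age, missing panel, liver
disease, hepatoprotectant), so a patient violating several rules always
reports the same reason. The shipped liver-disease prefix list
(`inst/extdata/liver_disease_icd10_synthetic.tsv`) is a synthetic
stand-in covering the targeted disease groups (B15--B19, K70--K77, C22);
the hepatoprotectant ATC list is the standard eight-substance list and
both are ordinary arguments of `cohort_criteria()`.

## Exposure features

A drug counts as an exposure when it was **newly started** within the 90
days before the index date (earliest prescription inside the window,
boundaries inclusive) and **continued to the index date**. Continuation
holds if a prescription exists on or before *and* on or after the index
date — a prescription on the index date itself counts for both sides — or
if the latest prescription date plus its days of supply strictly exceeds
the index date ("exceeds" is read strictly). The concomitant-drug count
applies the continuation rule alone, irrespective of start date.

The feature matrix is always `6 + 5 + D + P + C` columns: age at index
(floor of the year difference), male sex, one dummy per hospital, the
concomitant-drug count, five ICD-10 history flags (hypertension I10;
diabetes E10/E11/E14; dyslipidemia E78.0--E78.5; heart failure
I50.0/I50.1/I50.9; sepsis A40/A41), `D` frequent-drug flags, `P` product
terms and `C` therapeutic-class flags. A pair earns a product term when
its drugs are co-exposed in at least `pair_min_patients` patients
(default 100, scaled down proportionally for smaller cohorts in the
bundled analysis); the frequent-drug set is the union of drugs appearing
in at least one qualifying pair, and the remaining drugs are rolled up to
therapeutic classes through their ATC level-4 prefix. The real
chemical-subgroup-to-class assignment is not public, so the default map
names each class after its level-4 prefix; drugs with no mapping land in
an explicit `unclassified` class. Product columns are defined as the
elementwise product of their parent columns, so they are exactly 1 under
co-exposure at the index date and 0 otherwise.

## Models

Three classifiers share one contract (`alt_model`): coefficients on the
log-odds scale for the linear kinds, gain importances for the trees,
probabilities from `predict()`.

* `fit_mlr()` — maximum-likelihood logistic regression (`stats::glm.fit`)
  with a bounded iteration count. On wide collinear designs this model
  over-fits and can fail to converge; it then warns and flags
  `converged = FALSE` instead of raising, because that failure mode is
  itself part of the analysis.
* `fit_lasso_cv()` — L1-penalized logistic regression (glmnet) with
  10-fold cross-validation minimizing the *misclassification error rate*;
  the lambda grid is glmnet's standard path of 100 log-spaced values
  descending four decades from the all-zero lambda. Exact zeros are
  preserved. Under heavy class imbalance this criterion is conservative
  (the majority-class error is hard to beat), which matches its role as a
  shrinkage device rather than a probability calibrator.
* `fit_gbt()` — xgboost with a small booster grid (learning rate
  {0.1, 0.3} &times; depth {3, 6} &times; subsample {0.8, 1.0}), selected
  on a stratified inner 80/20 validation split by AUROC and refit on the
  full training set. The published grid is not available; ours is a
  documented, overridable default.

The 70/30 split is stratified by default (the source analysis does not
say; stratification keeps the roughly 93:7 control:case ratio in both
halves). Multiple logistic regression is fit once on all features jointly
rather than refit per pair — the per-pair covariate phrasing is ambiguous
and a single joint fit is the reading that keeps the three models
comparable on one design.

## Additive-scale interaction

For a pair with log-odds coefficients $\hat\beta_1$, $\hat\beta_2$ and
product term $\hat\beta_3$, the relative excess risk due to interaction
is

$$\mathrm{RERI} = e^{\hat\beta_1+\hat\beta_2+\hat\beta_3}
  - e^{\hat\beta_1} - e^{\hat\beta_2} + 1,$$

zero exactly when the combined odds-ratio excess equals the sum of the
individual excesses. Confidence intervals come from a percentile
bootstrap: 2,000 with-replacement resamples of the training rows (each of
full training size), coefficients refit on each, estimates sorted
ascending, interval read at ranks 50 and 1,950. For other replicate
counts $B$ the ranks generalize to $\max(1,\lfloor 0.025B\rfloor)$ and
$\min(B,\lceil 0.975B\rceil)$, which reduces to 50/1,950 at $B=2000$.
Ties are positional (stable sort). aOR intervals are the exponentiated
coefficient intervals — identical to percentile intervals of the aORs by
monotonicity. A resample that contains a single outcome class cannot be
refit and is redrawn with a logged count, keeping $B$ exact.

When the base model is the LASSO, each replicate refit reuses the lambda
selected on the original training set (`refit_lambda = "fixed"`). Whether
the original analysis re-ran the full cross-validation inside every
replicate is not stated; both modes are implemented, and fixed lambda is
the default because re-CV multiplies cost by the fold count while
targeting the same sampling distribution of the *selected* model. A
feature the penalty zeroes in part of the replicates produces a point
mass at zero in its bootstrap distribution, hence interval limits of
exactly 1.000 on the aOR scale — a signature visible in published
intervals of null drugs.

A pair is called **synergistic** only when both conditions hold: the
lower limit of the product-term aOR interval exceeds 1, and the lower
limit of the RERI interval exceeds 0.

## Evaluation

Confusion matrices need a threshold; none is stated in the source
analysis, and its predicted-positive rates (~27% at 7% prevalence) rule
out 0.5. We use the Youden-J-optimal threshold estimated on the training
ROC and applied to the test set, reported alongside the matrix, and
flagged as a reconstruction. Sensitivity, PPV, specificity and NPV are
reported as percentages; F1 on the 0--1 scale. AUROC and its DeLong
interval and the paired DeLong comparison come from pROC; AUPR is a
step-wise (average-precision) integration — no interpolation — because
trapezoidal PR integration is biased optimistic and the integration
choice changes the value. Undefined metrics (zero denominators) are `NA`
with a warning, never 0. Calibration curves use equal-width probability
bins with empty bins omitted.

## The synthetic generator

`generate_cohort()` emulates exactly the structures the pipeline
consumes: three liver-test days per patient (the minimum satisfying the
frequency rule) spaced by configurable gaps summing to at most 90 days;
an index date as the latest test day (internally day 0, converted to
calendar dates at the end); ALT trajectories consistent with the planted
outcome (cases in-range twice then above 132 U/L, controls always
in-range); AST/TBL/ALP on every test day; prescriptions placed so the
continuation and lookback rules reproduce the planted exposures by
construction, plus old-but-continued and discontinued background
prescriptions so the rules have negatives; and contamination classes each
violating exactly one exclusion rule. Ground truth (exposures, linear
predictor, outcome, concomitant count) lives in a sidecar table that the
pipeline never reads. `generate_design_matrix()` is the fast path that
skips the longitudinal layer and emits the design matrix and outcome
directly from the same logistic model.

Defaults are study conditions, not dials: baseline log-odds
`qlogis(0.07)` reproduces the ~93:7 class ratio; demographics and
comorbidity prevalences follow the published control-group
characteristics (age 58 &plusmn; 19, 42% male, hospital mix 78/11/11,
history prevalences 17/28/13/10/1%); control-range ALT is a truncated
normal centred at 16 U/L and case index ALT is 132 U/L plus a log-normal
with median ~50 (matching the published case median of ~180 U/L). No
per-drug exposure prevalence is published, so the generator defaults to
0.30 per drug; at that prevalence and $n = 5{,}000$ a planted pair with
aOR 1.5/1.5 and product-term aOR 2 gives roughly 95% Wald power for the
product term, which is why the recovery suite can demand a 90% detection
rate. The default seed is 20220706.

What the generator does **not** emulate: dose and duration effects,
realistic ICD-10 co-occurrence, correlated prescribing, seasonal or
between-hospital differences, informative lab-measurement timing. Tests
passing on this generator demonstrate that the machinery is correct under
its own model, not that the clinical findings replicate.

## Numerical choices and problem sizes

* Bootstrap refits use a compiled IRLS routine (RcppArmadillo) with a
  ridge fuzz of 1e-8 on the normal equations only when the solve fails;
  weights are floored at 1e-10 to survive separation-prone resamples.
* The recovery suite runs 100 repetitions of $n = 5{,}000$ patients,
  10 drugs, one planted pair (aORs 1.5/1.5/2.0) and three null pairs with
  $B = 500$ replicates each, checking ~95% RERI coverage, &ge;90%
  detection of the planted pair and &le;10% false synergy calls per null
  pair. The bundled analysis scripts use 6,000 patients and
  $B = 400$.
* RERI identities are asserted to 1e-12; logistic coefficients against an
  independent Newton-Raphson oracle to 1e-6; AUROC against the all-pairs
  concordance oracle to 1e-10.

## Limitations

The screen inherits every limitation of coefficient-based interaction
detection: LASSO shrinkage biases RERI toward the null (coverage
guarantees in the test suite are therefore stated for the unpenalized
fitter), percentile intervals of a penalized estimator have no exact
coverage theory, and the dual-criterion call is a decision rule, not a
test with a controlled error rate. The 1,375-feature arithmetic of the
original design (180 drugs, 1,050 pairs, 134 classes) cannot be
re-derived without the private data; the package reproduces the *identity*
`6 + 5 + D + P + C` on any input and pins the 1,375 total on a fixed
catalog.
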