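---
title: "Methods behind edscore: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind edscore: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscore)
```

`edscore` implements a complete pipeline for developing, validating and
applying a score for the total resource consumption of an emergency
department (ED) consultation, measured in tax points (TP) of the Swiss
TARMED outpatient tariff. This vignette documents the statistical model,
the synthetic cohort generator, and the numerical and design decisions the
package commits to, so that every constant in the code has a stated
rationale.

## The ln-linear resource model

Total TP per visit is strictly positive and right-skewed, so the model is
ordinary least squares on the natural logarithm:

$$\ln Y = a_0 + \sum_i \beta_i x_i + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

with binary predictors $x_i$ (dummy-coded categorical blocks for chief
complaint and age group, and 0/1 flags otherwise). Exponentiated
coefficients $e^{\beta_i}$ are reported as geometric mean ratios (GMR): the
multiplicative change in the geometric mean of total TP when the flag is
set. Confidence intervals are normal-theory Wald intervals on the ln scale,
exponentiated. `fit_univariable()` and `fit_multivariable()` return a
`gmr_table` carrying both the ln-scale coefficients and the GMR columns.

Coefficients are also stored at a ×10 scale rounded to one decimal
(`coef_x10`), which is the precision at which the published model is
communicated; predictions use `coef_x10 / 10` in the exponent so that the
printed table and the arithmetic agree exactly.

### The encoded published model

`published_score_spec()` returns the final published model: ln intercept
6.0 and 27 ×10 coefficients over 16 predictor blocks (chief complaint with
baseline *musculoskeletal*, age group with baseline *45–64*, six
vital-sign deviation flags, ambulance arrival, resuscitation-bay care,
three drug classes and three comorbidities). A worked example, computed
rather than quoted:

```{r worked}
spec <- published_score_spec()
x <- feature_profile(chief_complaint = "respiratory", age_years = 30,
                     ambulance = TRUE)
predict_total_resources(spec, x)   # exp(6.0 + 0.43 + 0.36 - 0.10)
compute_score(spec, x)
```

## The 0–100 score

The score is an affine rescaling of the ×10 coefficient sum:

$$\text{score} = c_0 \left(c_1 + \sum_i a_i x_i\right),$$

where `derive_score_constants()` chooses $c_1$ as minus the smallest
achievable coefficient sum (so the minimizing profile scores exactly 0) and
$c_0 = 100 / (\text{max sum} + c_1)$ rounded to one decimal (so the
maximizing profile scores approximately 100). Admissible profiles set
exactly one chief-complaint level and one age level (baselines count as
"none of the dummies"), with all flags free, so the extremes decompose
block-wise: each block contributes its most negative (or most positive)
coefficient, floored at the all-zero baseline. For the published
coefficients this yields $c_1 = 17.8$, $c_0 = 1.7$ and a maximum score of
$1.7 \times 59.2 = 100.64$ — the one-decimal rounding of $c_0$ (from
$100/59.2 = 1.689\ldots$) deliberately trades an exact 100 ceiling for
communicable constants.

```{r constants}
derive_score_constants(published_coefficient_table())[c("c0", "c1")]
```

## Predictor derivation

`derive_features()` maps a visit-level table to the 0/1 design matrix.
Decisions worth recording:

* **Vital-sign thresholds.** Flags are systolic blood pressure below
  100 mmHg (configurable via `sbp_threshold`; 90 is a common alternative
  cut and is supported, but 100 is the package default because it is the
  threshold under which the encoded final model was estimated), heart rate
  below 50 or above 110/min, Glasgow Coma Scale below 15, SpO₂ below 90%,
  respiratory rate below 8 or above 25/min, and temperature below 35.0 °C
  or above 38.5 °C, the comparisons being strict.
* **Missing vitals map to 0.** A missing measurement is treated as
  "deviation not documented", matching how such flags are ascertained from
  routine records; it keeps every record scorable.
* **Age groups** are 18–24, 25–44, 45–64 (baseline), 65–84 and 85+ with
  left-closed boundaries (a 65-year-old is in 65–84).
* Auxiliary features (triage dummies, sex, season, night, weekend,
  crowding bands, a trauma × resuscitation-bay interaction) support the
  comparison and sensitivity model variants but are not part of the final
  predictor set.

## Eligibility filtering

`apply_eligibility_filters()` excludes, in a fixed first-match order:
patients under 18; records whose administrative case id is missing or
shared by another presented record; visits with total TP below 10 (a
consultation cheaper than a few minutes of physician time indicates an
administrative artifact); visits led by a psychiatrist (different tariff
logic); and visits without a chief-complaint category. Each excluded record
is tallied under the *first* rule it violates, so the tallies sum to the
number of exclusions and the filter is idempotent on its own output.

## GMR-band pruning

`prune_by_gmr_band()` implements parsimony pruning: predictors whose
multivariable GMR lies strictly inside (0.9, 1.1) — a smaller than ±10%
multiplicative effect — are removed one at a time, refitting after each
removal. The removal order is deterministic: the in-band block closest to
the null (smallest maximum $|\ln \text{GMR}|$ over its dummies), with
alphabetical tie-breaking. Categorical blocks are removed whole or not at
all; a block qualifies only when *every* level is in-band. `protected`
predictors are never removed, and the last remaining predictor is kept. A
`refit_each_step = FALSE` mode removes all in-band predictors per round for
comparison. The one-at-a-time-with-refit default is tested against an
independent brute-force reimplementation of the rule.

## Split-sample validation

`validate_model()` splits the eligible cohort 50:50 at random
(`split_cohort()`), fits on the training half and evaluates on the
validation half. Metrics are computed on the ln scale, where the model is
linear and its error assumptions live: $R^2 = 1 - SSE/SST$, mean absolute
prediction error, mean squared prediction error and mean relative squared
error; AIC/BIC are Gaussian log-likelihood versions that agree exactly with
`stats::AIC()`/`BIC()` on the generating `lm` fit.

Calibration across the severity range is summarized by APDPOR — the
absolute percentage deviation of predicted from observed, $|100 -
100\,\hat y/y|$ — reported as median and interquartile range per decile of
the observed ln outcome. Deciles use empirical quantile breaks with
ties-to-lower assignment, so the decile counts are as equal as ties allow.
The ln scale is the default because the deviation is a ratio measure and
the model is estimated on ln TP; `ln_scale = FALSE` back-transforms first
for a natural-scale variant.

The comparison benchmark (`comparison_model_r2()`) is a triage-plus-age
model: what a nurse-assigned acuity category plus demographics alone would
predict. As external plausibility anchors the report also carries the
ln-scale correlation between total TP and billed cost.

## The synthetic cohort generator

No patient-level ED data ships with the package, so `generate_cohort()`
provides a generator whose *true* effects are known, making parameter
recovery testable end-to-end. Design choices and defaults
(`generator_config()`):

* **Outcome.** ln TP is generated exactly from the model: intercept 6.0,
  the encoded final-model coefficients divided by 10 as true ln effects,
  plus Gaussian noise. By default the noise variance is calibrated
  (`calibrate_residual_sd()`) so the population $R^2$ of the linear
  predictor is `target_r2 = 0.54`, the explanatory power regime the
  package's validation machinery is designed around; a fixed
  `residual_sd` can be supplied instead.
* **Resource categories.** Each visit's total is split into physician,
  nurse, laboratory, radiology and material TP with a Dirichlet draw whose
  mean shares are 54.8%, 5.4%, 16.2%, 19.2% and 4.5%. The concentration is
  the mean vector divided by 2, giving realistic visit-to-visit share
  dispersion. Category TP are stored rounded to 4 decimals and the total
  is their exact sum, so aggregation conservation holds to the last digit.
* **Demographics and covariates.** Marginal prevalences (sex, ambulance,
  resuscitation bay, vital deviations, drug and comorbidity markers,
  chief-complaint and age-group distributions) default to values typical
  of an adult tertiary ED. Comorbidity and drug prevalences rise with age
  through a logistic link in standardized age whose intercept is solved
  with `uniroot()` to preserve the configured marginal exactly.
* **Triage.** Acuity is drawn with a Gumbel-max categorical sampler whose
  logits are tilted by the standardized true linear predictor
  (`triage_acuity_tilt = 0.8`), so triage genuinely carries severity
  signal (the comparison model attains a meaningful but clearly lower
  $R^2$ than the full model) while keeping the configured marginal
  distribution approximately intact.
* **Ineligible admixture.** On top of the `n_visits` eligible records, a
  20% admixture of ineligible visits is appended, spread equally over the
  five exclusion reasons, so filter behaviour is exercised on every
  simulated cohort.
* **Ancillaries.** Billed cost is generated to correlate with TP at 0.939
  on the ln scale; ED length of stay is lognormal and weakly tied to the
  linear predictor (`los_coef = 0.3`, `los_sd = 0.5`); admission
  timestamps cover study years 2013–2017 with mildly growing yearly
  volumes and a day/night, weekday/weekend profile.

Its deliberate limits: independence of predictors given age, no seasonal
case-mix shift, and a correctly specified outcome model — the generator is
a test bed for the estimation machinery, not an epidemiological simulator.

## Crowding indices

`edwin()` computes $\text{EDWIN} = \sum_i n_i t_i / (N_a (B_T - B_A))$ with
the triage category number applied literally, banded as below 1.5 (active),
1.5–2.0 inclusive (very busy) and above 2 (overcrowded); the statistic is
degree-1 homogeneous in the census and degree −1 in attending staff, which
the tests verify. Occupancy is patients present divided by treatment beds.
`compute_crowding()` evaluates both at every admission instant from the
concurrent visits in the cohort, using sorted `findInterval()` counting
(O(n log n)); when boarding patients fill all beds EDWIN is undefined and
returned as missing with a warning.

## Benchmarking

`benchmark_years()` aggregates visits, cumulative resource-score points
(RSP) and points per visit and per clinical full-time staff member by
calendar year, with relative changes against the first year. Changes are
kept unrounded in the table and rendered in the conventional `+10%` /
`+/-0%` style only by the print method.

## Numerical and testing choices

Fits use `stats::lm()` via QR decomposition; no hand-rolled linear algebra.
Randomness is reproducible: every stochastic entry point takes a seed, and
identical configurations produce bit-identical cohorts. The test suite
pins hand-computable cases exactly (worked example, score constants, EDWIN
snapshots, filter tallies), checks estimator behaviour against independent
re-implementations (pruning brute force, decile recomputation,
`stats::AIC`, `cor.test`), and verifies statistical properties at
simulation sizes chosen so that Monte-Carlo noise is far smaller than the
tested tolerances (marginal prevalences at n = 50 000 within three binomial
standard errors; realized $R^2$ within ±0.02–0.03 at n = 10 000–100 000;
confidence-interval coverage pooled over replicates and coefficients
against the nominal 95% with a 90% floor, since per-coefficient coverage
over few replicates is binomially noisy by construction).
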