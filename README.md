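# edscore

Develop, validate and apply a 0–100 score for the **total resource
consumption of an emergency department (ED) consultation**, measured in tax
points (TP) of the Swiss TARMED outpatient tariff.

ED crowding makes it valuable to estimate, from information available at
presentation, how resource-intensive a consultation will be. `edscore`
packages the full methodology:

* an **ln-linear regression model** of total TP whose exponentiated
  coefficients are geometric mean ratios (GMR) — the multiplicative change
  in typical resource use associated with each presentation characteristic
  (chief-complaint category, age group, deviating vital signs, ambulance
  arrival, resuscitation-bay care, drug intake, comorbidities);
* **GMR-band pruning** to a parsimonious final model (predictors with GMR
  inside 0.9–1.1 are removed stepwise with refitting);
* a **0–100 resource score** derived from the ×10-scaled coefficients, with
  constants chosen so the minimum admissible profile scores exactly 0;
* **split-sample validation** (R², error metrics, AIC/BIC, and APDPOR — the
  absolute percentage deviation of predicted from observed — by decile of
  the observed outcome) plus a triage-plus-age comparison model;
* **ED crowding indices** (EDWIN and occupancy) computable per visit from
  concurrent presence in the cohort;
* **year-over-year benchmarking** of cumulative resource-score points per
  visit and per clinical staff member;
* a **synthetic cohort generator** with known true effects, so the entire
  pipeline is testable end-to-end without patient data, and a **command
  line interface** (`inst/cli/edscore`) wiring it all together.

The encoded published model has ln intercept 6.0 and 27 coefficients over
16 predictor blocks; its score constants are c₀ = 1.7 and c₁ = 17.8.

## Worked example

A 30-year-old patient with a respiratory chief complaint, normal vital
signs, no relevant drugs or comorbidities, brought in by ambulance:

```r
library(edscore)
spec <- published_score_spec()
x <- feature_profile(chief_complaint = "respiratory", age_years = 30,
                     ambulance = TRUE)

predict_total_resources(spec, x)
#> [1] 804.3223
compute_score(spec, x)
#> [1] 41.99
```

The prediction is `exp(6.0 + 0.43 + 0.36 - 0.10)` ≈ 804 TP: respiratory
complaint (+0.43 on the ln scale), ambulance arrival (+0.36) and age group
25–44 (−0.10) on top of the intercept. The score is
`1.7 × (17.8 + 4.3 + 3.6 − 1.0) = 41.99`.

The score constants are re-derivable from the coefficient table:

```r
derive_score_constants(published_coefficient_table())[c("c0", "c1")]
#> $c0
#> [1] 1.7
#>
#> $c1
#> [1] 17.8
```

End-to-end on synthetic data — generate a cohort with known true effects,
filter it, and run the split-sample validation:

```r
cfg <- generator_config(n_visits = 20000, seed = 7)
coh <- apply_eligibility_filters(generate_cohort(cfg))$eligible
validate_model(coh, seed = 1)
#> Split-sample validation: n = 10,000 training / 10,000 validation
#>   validation R2 = 0.533; MAPE 0.448, MSPE 0.315, MRSE 0.0083
#>   training AIC 17101.4, BIC 17310.5
#>   triage + age comparison model R2 = 0.160
#>   ln resources vs costs: r = 0.937 (95% CI 0.935-0.940)
#>   APDPOR by decile of observed ln outcome (%):
#>     1. decile   12.9  (6.0, 19.3)
#>     2. decile   10.5  (6.9, 14.1)
#>     3. decile    5.8  (2.5, 9.5)
#>     4. decile    3.8  (1.9, 6.9)
#>     5. decile    3.5  (1.7, 5.9)
#>     6. decile    3.4  (1.9, 6.1)
#>     7. decile    4.0  (1.8, 6.9)
#>     8. decile    5.0  (2.5, 8.3)
#>     9. decile    6.6  (3.6, 9.9)
#>    10. decile    9.2  (5.6, 12.8)
```

A hand-checkable crowding snapshot — four triage-3 patients, two attending
physicians, five beds of which two are blocked by boarding patients:

```r
edwin(crowding_snapshot(c(0, 0, 4, 0, 0), n_attending = 2,
                        beds_total = 5, boarding = 2))
#> $score
#> [1] 2
#>
#> $band
#> [1] "very busy"
```

The same pipeline is scriptable from the shell via `inst/cli/edscore`
(`simulate`, `fit`, `score`, `validate`, `benchmark`, `crowding`).

## Documentation

See the methods vignette (`vignettes/edscore-methods.Rmd`) for the model,
the score construction, the generator design and every numerical decision,
and the function reference for interfaces.

## License

MIT (see `LICENSE`).
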