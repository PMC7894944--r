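Package: edscore
Title: Emergency Department Resource Consumption Scoring and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop, validate and apply a score for the total
    resource consumption of an emergency department (ED) consultation,
    measured in tax points (TP) of the Swiss TARMED outpatient tariff.
    Provides a synthetic ED-visit cohort generator with known true effects,
    eligibility filtering and predictor derivation (vital-sign deviation
    flags, chief-complaint and age groups, comorbidity and drug markers),
    univariable and multivariable ln-linear regression reported as geometric
    mean ratios (GMR), stepwise GMR-band pruning to a parsimonious model,
    derivation of a 0-100 resource score, split-sample validation with
    decile calibration statistics (APDPOR), ED crowding indices (EDWIN and
    occupancy), and year-over-year performance benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
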