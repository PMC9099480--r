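Package: nutricea
Title: Markov Cohort Cost-Effectiveness Model of Inpatient Nutritional Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state daily-cycle Markov cohort model for the health-economic
    evaluation of individualized nutritional support in hospitalized chronic
    heart failure patients. Implements deterministic cohort simulation with an
    individual-level microsimulation cross-check, per-state cost and utility
    accrual, incremental cost-effectiveness ratios, deterministic and
    probabilistic (Gamma-input) sensitivity analyses, willingness-to-pay
    threshold analysis, calibration of arm-specific transition matrices to
    trial-level targets (per-state life days and 180-day mortality), and a
    synthetic-trial generator with maximum-likelihood transition-matrix
    estimation for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
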