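Package: lungcea
Title: Cost-Effectiveness Modelling of First-Line Immunochemotherapy in
    Advanced Non-Small Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-state (progression-free, progressed, dead) cohort model
    for the cost-effectiveness of toripalimab plus chemotherapy against
    chemotherapy alone as first-line treatment of advanced non-small cell
    lung cancer, from the Chinese payer perspective. Weibull
    accelerated-failure-time survival extrapolation, cohort traces with
    half-cycle correction and discounting, incremental cost-effectiveness
    ratios and net monetary benefit, one-way (tornado) sensitivity
    analysis, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, reconstruction of pseudo individual-patient data
    from digitized Kaplan-Meier curves, and a seeded synthetic survival
    data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
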