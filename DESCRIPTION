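Package: radcea
Title: Cost-Effectiveness Modelling of Prostate Radiotherapy Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state Markov cohort model (failure-free survival,
    progressive survival, death) for comparing ultra-hypofractionated with
    conventionally fractionated radiotherapy in intermediate- to high-risk
    localized prostate cancer. Provides Weibull survival calibration from
    Kaplan-Meier milestones or digitized curve points, time-dependent
    transition probabilities, discounted cost and QALY accumulation,
    incremental cost-effectiveness ratios and net monetary benefit,
    one-way deterministic sensitivity analysis, probabilistic sensitivity
    analysis with beta/gamma parameter distributions, cost-effectiveness
    acceptability curves, threshold searches, biologically effective dose
    calculations, and a synthetic Kaplan-Meier data generator for
    end-to-end testing of the fitting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
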