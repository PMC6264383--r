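Package: gradnf
Title: Simulation and Analysis of Graded fMRI Neurofeedback Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing graded real-time fMRI
    neurofeedback experiments on region-of-interest (ROI) mean BOLD time
    series. Builds block designs for localizer and neurofeedback runs with
    counterbalancing, simulates ROI time series with hemodynamic responses,
    AR(1) noise, drift and task-coupled physiological traces, replicates the
    causal online feedback computation (moving-average percent signal change
    against a rest-block median baseline, mapped to thermometer segments),
    fits offline GLMs with AR(1) prewhitening and pre-onset baseline
    predictors, and reproduces the group-level inference layer: median
    percent-signal-change aggregation, 2x2 repeated-measures ANOVA with
    omega-squared, paired t-tests with Cohen's d, informed
    half-normal-prior Bayesian t-tests, and physiological-confound
    correlation analysis with Fisher z transform and FDR correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
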