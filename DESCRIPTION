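Package: lifespanqc
Title: Quality Control and Cross-Study Harmonization of Animal Lifespan Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-control toolkit for right-censored animal lifespan
    cohorts. Provides a plain-text lifespan data and metadata format,
    Kaplan-Meier and Nelson-Aalen estimators aligned to the experiment's
    measurement grid, maximum-likelihood Weibull and Gompertz fits with
    delta-method standard errors, an intra-study extra-mortality test that
    flags implausibly large single drops of the survival curve against
    parametric resampling nulls, a balanced meta-control built by
    inverse-variance (DerSimonian-Laird) combination of per-study Weibull
    parameters, an inter-study plausibility test based on a weighted
    two-dimensional Gaussian reference over Weibull parameters and
    Hotelling's T-squared statistic, a synthetic cohort generator for
    calibration studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    metafor
Config/testthat/edition: 3
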