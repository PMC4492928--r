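Package: forgetfit
Title: Retention Functions and Model Comparison for Savings Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of savings ("relearning") experiments in
    the Ebbinghaus tradition.  Computes savings scores from learning and
    relearning times, aggregates them into retention curves, and fits a
    family of classical retention functions -- Ebbinghaus' 1880 double-power
    and 1885 logarithmic equations, power functions with and without a
    constant post-24-hour "boost", summed exponentials, the two-store
    memory-chain consolidation model, and a single exponential -- by
    multi-start bounded nonlinear least squares.  Models are compared by sum
    of squared deviations, uncentered R-squared and a Gaussian-likelihood
    AIC.  Also provides serial-position (primacy/recency) analysis,
    summary-statistic one-way ANOVA, learning-time drift and time-of-day
    corrections, a seeded generator of synthetic savings experiments, and
    the printed data tables of a published single-subject replication as
    plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
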