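Package: prrtools
Title: Statistical Evaluation of Baseline-Change Associations in
    Recovery Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for deciding whether associations between baseline
    impairment and subsequent change in recovery studies are real or
    artifacts of mathematical coupling and regression to the mean.
    Implements the closed-form coupling surface relating cor(x, y - x) to
    cor(x, y) and the variance ratio var(y)/var(x), Oldham's method,
    bootstrap inference for the variance ratio and the baseline-follow-up
    correlation against non-standard null values, five candidate recovery
    models (intercept-only, constant recovery with a ceiling via censored
    regression, exponential, penalized-spline additive, and the
    proportional recovery rule) compared by cross-validated median
    absolute prediction error, and a Gap-statistic resampling test of
    observed cluster structure against a random-recovery null. Includes
    seeded generators for bounded bivariate-normal cohorts, constant
    recovery with a hard ceiling, and random recovery, plus a
    command-line interface for end-to-end analyses of cohort CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    minpack.lm,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
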