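Package: lifetherm
Title: Life Tables and Thermal Response Curves for Insect Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds stage-structured life tables from individual-level
    cohort inspection records collected at constant temperatures,
    converts stage durations to development rates, and fits the standard
    catalogue of temperature-dependent development (Logan, Briere,
    Sharpe-De Michele, Lactin-1/2), mortality (quartic bathtub, Kim-Lee),
    adult longevity and fertility response functions by bounded
    multi-start nonlinear least squares, with a goodness-of-fit battery
    (R-squared, RMSE, chi-squared, degrees of freedom) and model ranking.
    Ships published Drosophila suzukii constant-temperature life-table
    summaries as fixtures and a seeded synthetic-cohort generator that
    emulates the rearing design (cohorts of 50 eggs at 14 temperatures,
    temperature-dependent inspection intervals, per-couple daily egg
    counts) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
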