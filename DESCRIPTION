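Package: tempmort
Title: Temperature-Related Cardiovascular Mortality and Regional Vulnerability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of temperature-related cardiovascular mortality.
    Stage one fits a per-region Poisson regression with fixed-df natural spline
    smooths (a generalized additive model with regression splines) relating daily
    death counts to hinge terms in lagged temperature beyond the 10th/90th
    percentile thresholds, and reports the percent change in mortality per 1 degree
    Celsius beyond each threshold. Stage two discretizes region-level socioeconomic
    and demographic factors, labels regions as low or high risk from the estimated
    percent changes, and learns a discrete Bayesian network over factors and risk
    by simulated-annealing structure search with BIC scoring, with exact
    enumeration inference, marginal conditional probability tables, and two-fold
    cross-validation (probability of detection, probability of false alarm,
    accuracy). Includes inverse-distance-weighted interpolation of station weather
    to region series via zonal averaging, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
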