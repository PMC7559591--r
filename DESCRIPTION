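Package: incproj
Title: Benchmarking Statistical Approaches to Incidence Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting and comparing a ladder of increasingly complex
    models for projecting registry-style incidence counts: constant rate/count
    forward projections, negative-binomial generalized linear and additive
    models, a Bayesian tensor-product spline smoother, and a Bayesian
    age-period-cohort (APC) model with second-order random-walk priors and an
    overdispersion effect. Projections carry full predictive distributions and
    are scored by coverage of equal-tailed 95% intervals, relative bias and
    averaged predictive standard deviation in a rolling hold-out design, with
    probability-integral-transform histograms for calibration checks. A
    synthetic-registry simulator with known age, period and cohort structure
    supports calibration and parameter-recovery studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    splines,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    optparse
Config/testthat/edition: 3
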