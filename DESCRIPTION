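Package: timeswap
Title: Compositional Isotemporal Substitution Modelling of 24-Hour Time Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how reallocations of time between daily
    activities (sleep, screen time, physical activity, quiet time, passive
    transport, school-related and domestic/self-care activities) are
    associated with health outcomes. The seven-part 24-hour activity
    composition is expressed in isometric log-ratio (ilr) coordinates and
    entered, together with second-order polynomial terms and covariates,
    into ordinary least squares regression models. Fitted models are
    serialized as privacy-preserving JSON artifacts (coefficients,
    covariance and degrees of freedom only), from which the difference in
    outcome between any two time-use compositions is estimated with 95%
    confidence intervals: a linear contrast for identity-scale outcomes and
    the method-of-variance-estimates-recovery (MOVER) interval of Zou for
    log-transformed outcomes. Includes zero replacement for below-detection
    durations, a seeded synthetic data generator with known ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
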