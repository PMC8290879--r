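Package: stridesla
Title: Stride-by-Stride Predictors of Step Length Asymmetry in Hemiparetic Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing within-subjects and between-subjects variance
    in step length asymmetry (SLA) during hemiparetic treadmill walking.
    Extracts stride-level temporal, kinematic and kinetic gait variables from
    marker and force-plate time series (gait-event detection from malleolus
    excursions, sagittal joint angles, ground-reaction-force impulses and
    peaks, planar link-segment inverse dynamics), assembles stride-level
    feature matrices, and relates SLA magnitude to 40 candidate predictors by
    multilevel sparse partial least squares regression with exhaustive
    leave-one-out cross-validation and one-standard-error model selection.
    Selected models are validated with random-intercept linear mixed models
    (coefficient confidence intervals, marginal and conditional R-squared) and
    participant-level bootstrap. Includes synthetic gait-signal and
    feature-level data generators with exact ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
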