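Package: rpvent
Title: Ventilation-Weighted Dose Features and Radiation Pneumonitis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 4D-CT based lung ventilation images from registered
    inhale/exhale CT pairs and deformable-registration displacement fields
    (Hounsfield-unit and Jacobian-determinant metrics), converts planned dose
    to its 2 Gy/fraction equivalent (EQD2) under the linear-quadratic model,
    extracts dose-volume and dose-function histogram features of the healthy
    lung, and evaluates radial-basis-function support-vector-machine models
    of grade >= 2 radiation pneumonitis over nested feature sets with
    repeated stratified splits, Bayesian hyperparameter optimization and
    nonparametric statistics. A parametric phantom-cohort generator with
    analytically known deformation Jacobians makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
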