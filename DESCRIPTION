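Package: chillfit
Title: Inverse Estimation of Thermal Properties from Cylinder Chilling Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical series solver for transient heat conduction in a
    finite cylinder with convective (third-kind) boundaries, coupled to a
    damped (Levenberg-Marquardt) least-squares estimator that recovers
    thermal diffusivity and the reduced heat transfer coefficient, with
    covariance-based uncertainties, from a measured centre-point cooling
    curve. Includes moisture-based thermophysical property correlations
    (Fikiin, Riedel, Sweat), Biot-number regime classification, temperature
    field export, a synthetic cooling-curve generator for Monte-Carlo
    calibration, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
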