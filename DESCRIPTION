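Package: alcidkin
Title: Wing Kinematics and Strouhal Numbers of Dual-Medium Flight from
    Video Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn digitized video landmarks (eye, tail, shoulder,
    wrist, wingtip) of birds flying in air or water into per-flight wing
    kinematics: wingbeat segmentation, wing excursion and frequency,
    stroke-plane and chord angles, wingbeat amplitude and stroke velocity,
    pitch-corrected translational velocity, and Strouhal numbers with
    propagated standard deviations. Coordinates are self-calibrated to
    body lengths with two-stage smoothing splines, and descending
    trajectories are rotated into a path-aligned frame. Includes a forward
    simulator of a flapping, diving bird so the whole pipeline is testable
    by parameter recovery, plus the statistical workflow used for
    air-versus-water comparisons: log-transformed linear models with
    sequential (type I) ANOVA and eta-squared, Tukey HSD post hoc tests,
    Welch t-tests with Bonferroni correction, and a studentized-residual
    outlier test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
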