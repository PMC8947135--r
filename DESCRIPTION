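Package: flighttunnel
Title: Stereo Videogrammetry and Flight-Performance Analysis for Tunnel Experiments with Obstacle Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A measurement-and-inference pipeline for insect flight experiments in
    obstacle-field tunnels: synthetic generation of ground-truth flights and stereo
    camera observations, background-subtraction blob detection, constant-velocity
    Kalman tracking with Munkres assignment, two-view triangulation, quintic-spline
    trajectory smoothing, flight-performance metrics (altitude, route choice, ground
    speed, lateral excursion), and random-intercept linear mixed models with
    stratum-specific residual variances, AIC model selection and Tukey-adjusted
    marginal contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    nlme,
    emmeans,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
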