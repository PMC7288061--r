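Package: bodycekf
Title: Physically Consistent Whole-Body Kinematics from RGB-D Joint Centers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained extended Kalman filtering of noisy 3D joint-center
    positions, as produced by RGB-D skeleton trackers, into physically
    consistent whole-body joint angles. Provides a 22-degree-of-freedom
    kinematic chain with forward kinematics and analytic Jacobians, a
    restricted-gain constrained EKF that enforces physiological joint limits
    and constant segment lengths, data-driven (spectral) and
    optimization-based tuning of the process-noise covariance, per-frame
    least-squares inverse kinematics for initialization and reference
    trajectories, a synthetic rehabilitation-task generator with a
    depth-camera noise model, and an evaluation suite (RMSD, Pearson
    correlation, one-dimensional statistical parametric mapping with
    random-field-theory and permutation inference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
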