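Package: gloveforge
Title: Simulation-Driven Design of Sensor-Instrumented Gloves for Gesture
    Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for designing smart gloves from motion data alone.
    Noisy 3D hand key-point trajectories are aligned to a 26 degree-of-freedom
    kinematic right-hand model (mirroring, per-segment scaling, wrist
    translation and Kabsch rotation), converted to joint-angle motions by
    constrained per-frame inverse kinematics, and enlarged by hand-size and
    key-pose time-warp augmentation. Inertial measurement unit readings
    (accelerometer, gyroscope, magnetometer) are synthesised at 15 candidate
    phalanx sensor sites from simulated sensor trajectories, candidate sites
    are ranked by joint-angle independence and correlation scores, and
    sliding-window gesture classifiers are trained and evaluated per candidate
    sensor set to produce a design report. A synthetic gesture generator makes
    the whole pipeline testable without external motion datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    ranger,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
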