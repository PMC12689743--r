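Package: arnav
Title: Markerless Augmented-Reality Surgical Navigation Core
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free computation core for markerless augmented-reality
    surgical navigation. Registers a preoperative organ surface model to
    masked RGB-D depth frames with point-to-point ICP, bypasses algorithmic
    latency by forecasting the registration transform with Double
    Exponential Smoothing (vector arithmetic for translations, quaternion
    SLERP for rotations), implements the multi-device calibration chain and
    Horn's closed-form fiducial registration, and evaluates accuracy with
    target registration error, Chamfer distance, intersection-over-union,
    visibility factor and success rate. A deterministic simulator generates
    liver-like phantom meshes, turning-wheel rigid trajectories, rendered
    depth and mask frames, occlusion scenarios and calibration scenes, so
    the full pipeline can be exercised and tuned without cameras, trackers
    or a head-mounted display.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
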