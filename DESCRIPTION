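Package: fallkin
Title: Accuracy of Planar-Video Fall Kinematics Against 3D Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how accurately body-segment kinematics of
    falls can be measured from standard surveillance-grade planar video
    (30 Hz, 640x480) digitized frame-by-frame, using high-speed 3D optical
    motion capture as ground truth. Implements the full validation pipeline:
    dual-pass Butterworth filtering and spectral screening of ground-truth
    trajectories, pixel-to-metre calibration by planar grid homography or a
    1D height scale (with grid translation/rotation and height-error
    perturbations), cubic-spline upsampling, cross-correlation
    synchronization, central-difference velocities, absolute segment angles,
    and RMSE / normalized RMSE / peak-velocity accuracy metrics. A seeded
    synthetic fall generator (linked-segment minimum-jerk templates with a
    translating-platform perturbation and out-of-plane excursions) and a
    pinhole camera observer let every analysis run end-to-end without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse,
    knitr
Config/testthat/edition: 3
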