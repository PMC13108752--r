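Package: hpeval
Title: Validation of Markerless 3D Pose Estimation Against Optical Motion Capture for Gesture Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate markerless human pose estimation (HPE) against
    optical motion capture (MoCap) for three-dimensional gesture research.
    Implements confidence-gated stereo triangulation of per-camera 2D keypoint
    streams through a calibrated pinhole model, temporal alignment (clapperboard
    trimming, margin exclusion, uniform downsampling) and spatial alignment
    (validity masking, tape-measure scaling, SVD rigid registration) onto a
    MoCap reference, per-keypoint Euclidean-error tables with repeated-measures
    ANOVA and Bonferroni post-hoc statistics, voxelized gesture-space occupancy
    with Dice similarity, and a synthetic gesture-session generator that
    emulates the full multi-camera study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
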