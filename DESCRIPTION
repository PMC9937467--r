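Package: facetouch
Title: Face-Touch Detection from Wrist-Worn Inertial Sensors via Dynamic
    Time Warping and k-Nearest Neighbours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects hand-to-face gestures from wrist-mounted inertial
    measurement unit (IMU) recordings.  Implements the full detection
    pipeline: zero-phase Butterworth filtering, gravity-based vertical
    alignment, down-sampling and quantization; refinement of self-reported
    face-touch instants from the angular-velocity magnitude; template
    matching with exact dynamic time warping and the multilevel FastDTW
    approximation in a 3-second sliding window; an 8-dimensional DTW-score
    feature space; k-nearest-neighbour majority-vote classification with
    70/30 splits and leave-one-subject-out cross-validation; and
    event-level detection metrics (sensitivity, precision, accuracy, FPR,
    FDR).  Includes a seeded synthetic wrist-gesture simulator
    (minimum-jerk reach-dwell-return kinematics with confounding gestures)
    so every stage is testable without human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
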