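Package: ergopose
Title: Ergonomic Posture Assessment from 2D Human-Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes streams of 2D human-pose keypoints (18-point
    upper-body skeletons from any pose estimator) into postural parameters
    for seated desk work: neck lateral bend, shoulder alignment and
    left/right arm abduction. Angles are computed from keypoint pairs with a
    piecewise atan2 formulation, classified into ergonomic range-of-motion
    zones 0-3 and a safe/dangerous two-class collapse, and turned into
    sustained-posture alerts and session summaries. Includes the full
    evaluation machinery (confusion matrices, per-class one-vs-rest
    accuracy, critical-error counts, repeated 50%-subsample evaluation with
    MIN/MAX/MEAN/STD summary rows) and a synthetic labelled-skeleton
    generator so every stage is testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
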