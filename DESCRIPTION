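Package: autopatchr
Title: Simulation and Control Algorithms for Image-Guided Automated Patch Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational core of a label-free image-guided automated
    patch-clamp workflow: synthetic differential-interference-contrast
    (DIC)-like image phantoms with ground truth and a simulated
    electrophysiology rig; multi-page TIFF stack and bounding-box
    annotation input/output with background illumination correction;
    pipette tip localization by fitting a two-cylinder pipette model with
    gradient descent and micromanipulator-to-stage calibration; per-slice
    cell detection with Z-axis merging of bounding boxes into 3D
    detections; centroid-distance detection evaluation (precision, recall,
    F1); lateral (pyramidal Lucas-Kanade) and axial (focus-difference)
    cell tracking; and the complete autopatching state machine (hunting
    with obstacle avoidance, descent and contact detection, gigaseal
    formation with escalation protocols, break-in, pipette cleaning,
    cytoplasm harvesting) with an event diary and report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
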