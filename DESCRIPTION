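Package: shredmorph
Title: Morphometry and Detection Evaluation for Blended Tobacco-Shred Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the two-dimensional size (length and width)
    of curved plant-material fragments, such as tobacco shreds, in calibrated
    RGB images. Implements background-shadow elimination for scenes of dark
    fragments on a light ground, a strip-sliced centerline algorithm for the
    length of bent objects, maximum-inscribed-circle width profiling via the
    distance transform, single-stage detection-network components (residual
    multi-branch backbone blocks, serial spatial-pyramid pooling, a decoupled
    detection head, complete-IoU loss), and detection evaluation (precision,
    recall, average precision, mAP over IoU thresholds). A synthetic scene
    generator with exact ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
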