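Package: gazebattery
Title: Event Detection and Task-Battery Measures for Low-Sample-Rate Webcam Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ~30 Hz webcam-based eye tracking: screen
    geometry and robust-statistics primitives, a synthetic five-task battery
    simulator (fixation, zone classification, free viewing, smooth pursuit,
    cued blinks) with known ground truth, event detection tailored to low
    sampling rates (spatio-temporal density fixation clustering,
    dynamic-programming and penalized changepoint segmentation for smooth
    pursuit onset/offset and blinks, eye-aspect-ratio support), per-task
    quantitative measures, fixation heatmaps with AUC/CC/SIM saliency
    indices, and hierarchical winsorized aggregation for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
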