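Package: somnipose
Title: Sleep Posture Monitoring from Paired Chest and Wrist Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for recognising gross sleep postures (supine, prone,
    left/right lateral, standing) from wearable tri-axial accelerometers.
    During a training session a chest-worn sensor is calibrated by a planar
    rotation, denoised, and converted to per-second posture labels by
    dominant-axis rules; a wrist-worn sensor is segmented into one-second
    frames whose per-axis means form the feature matrix. The joined design
    matrix trains either a one-against-all support vector machine with an
    RBF kernel and literal vote tallying, or a random forest with a
    tree-count selection protocol, so that during monitoring only the wrist
    sensor is needed. Includes readers/writers for the raw brace-delimited
    sensor dialect and CSV, a synthetic two-sensor session simulator with
    known ground truth, and evaluation tools (confusion matrices, repeated
    train/test trials, cross-subject transfer, multi-session summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
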