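Package: posturekit
Title: Marker-Based Photogrammetric Posture Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for static posture assessment from four-view photographs
    (anterior, posterior, left and right lateral) of a subject wearing
    colored spherical markers on standard anatomical sites.  Detects markers
    by HSV color thresholding and shape-filtered blob detection, calibrates
    pixel coordinates to a metric gravity-aligned frame from an in-scene
    scale rectangle and plumb line, computes 38 anatomical angle and
    distance features, statistically validates two measurement sources
    against each other (normality-gated paired tests and TOST equivalence
    with a boundary ladder), and screens for postural-problem evidence with
    multiclass and two-level binary-cascade LDA/kNN classifiers.  Includes a
    fully ground-truthed synthetic scene and population generator so every
    stage is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    EBImage,
    MASS,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
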