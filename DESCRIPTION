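Package: nervemorph
Title: Histomorphometry and Segmentation Evaluation for Peripheral Nerve
    Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmenter-agnostic toolkit for quantitative morphometry of
    myelinated nerve fibers in light-microscopic cross-sections. Converts
    three-class axon/myelin semantic masks into per-fiber instances and
    computes equivalent-circle axon diameter, myelin sheath thickness,
    g-ratio and shape descriptors; scores predicted masks against ground
    truth at pixel level (overlap, Jaccard, Dice, false positive/negative
    error) and object level (precision, sensitivity, F-score); quantifies
    per-fiber method agreement with Bland-Altman analysis; orchestrates
    patch-based tiled segmentation with a pluggable per-patch segmenter
    and a classical intensity-threshold baseline; and generates synthetic
    osmium-stained nerve cross-section phantoms with exact ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    optparse,
    tibble,
    stats,
    grDevices,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
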