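Package: seedcount
Title: Desk-Scale Seed Counting by Image Processing with Detection
    Post-Processing and Evaluation Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Counts seeds in photographs of seeds spread on a uniform
    background using a classical image-processing pipeline (grayscale
    conversion, Gaussian smoothing, automatic Otsu thresholding,
    connected-component segmentation, external contour tracing, and
    millimetre-calibrated feature extraction), and provides the
    post-processing chain used by single-stage object detectors (box
    decoding, confidence filtering, non-maximum suppression) together
    with PASCAL-style detection metrics (IoU, precision, recall, F1,
    average precision, mAP) and replicate count summaries (mean and
    standard error). A deterministic synthetic seed-image generator
    produces ground-truthed fixtures emulating seeds on white A4 paper,
    orange, or black table surfaces, so every stage is testable without
    photographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
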