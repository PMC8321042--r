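Package: her2cascade
Title: Multi-Stage Multiple-Instance Pipeline for Slide-Level HER2 Status from H&E Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staged pipeline that predicts slide-level HER2 status from
    rasterized haematoxylin-eosin whole-slide images: regular-grid tile
    extraction with mean-grayscale background filtering, an optional
    cancer-tile pre-filter, a per-tile HER2 probability classifier trained
    under weak (slide-level) labels, slide-level multiple-instance features
    (positivity indices P1/P2/P3 and probability-histogram frequencies Fh),
    and two aggregation strategies (majority vote over the indices, or a
    small fully-connected tabular learner on P1* and Fh). Includes a
    synthetic-slide and synthetic-probability-bag generator with planted
    ground truth so the whole cascade is testable at desk scale, plus
    confusion-matrix evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
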