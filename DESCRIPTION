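Package: tpdia
Title: Digital Image Analysis of Thyroid FNA ThinPrep Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nuclear morphometry pipeline for thyroid fine-needle aspiration
    (FNA) cytology on ThinPrep preparations. Segments nuclei from RGB field
    images (background subtraction, green-channel extraction, automatic
    thresholding), measures each connected particle with an ImageJ-style
    measurement set (area, perimeter, circularity, Feret diameters, solidity,
    fitted-ellipse aspect ratio, and intensity statistics), gates particles
    into single nuclei versus overlapping clusters, aggregates an 86-feature
    per-image vector organised into cellularity, architecture, chromatin,
    shape and size models, and classifies follicular adenoma versus benign
    thyroid with gradient-boosted and extremely randomized tree ensembles
    under a repeated 1:1 split protocol. Includes a parametric synthetic
    field-image generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    ranger,
    stats,
    tiff,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
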