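Package: vesselmorph
Title: Vessel Wall and Lumen Morphometry for Arteriolosclerosis Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry of cross-sectioned blood vessels in
    digital-pathology image tiles. Implements recursive centering of tiles
    onto detected vessels (ORCA), conversion of pixel-wise segmentations
    into tile-level confidence scores, and automated vascular morphometry
    from wall/lumen segmentation masks: sclerotic index, wall thickness by
    a tangent-line method and by a radii method, and the wall-to-lumen
    area ratio in physical units. Ships a seeded synthetic vessel phantom
    generator with analytic ground truth, a classical reference segmenter,
    segmentation evaluation metrics (Dice, Hausdorff, AUC-ROC), and an
    end-to-end tiling pipeline, so every stage is testable without
    whole-slide images or trained neural networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
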