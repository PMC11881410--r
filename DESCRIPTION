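Package: histonox
Title: Automated Nuclear Morphometry and Texture Scoring for Skin Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automated detection and morphometric quantification of
    nuclei in large hematoxylin-eosin stained skin-section images. Provides
    tissue region-of-interest detection, stain deconvolution, tiled nucleus
    instance segmentation with cross-tile label merging, epidermis
    segmentation, per-nucleus shape/intensity/texture/density descriptors
    including a masked gray-level co-occurrence (GLCM) contrast score
    computed over each nucleus and its perinuclear margin (the "high
    contrast mean", a marker of UV- and oxidative-stress nuclear damage),
    sample summaries, two-group statistics (Welch/Student/paired t, SSMD,
    PCA, LDA), Deep Zoom pyramid export, and a seeded synthetic slide
    generator with exact ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
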