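Package: rsomvasc
Title: Multiscale Skin Microvascular Morphometry and Reactivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for volumetric dual-frequency-band optoacoustic
    mesoscopy (RSOM) images of skin microvasculature. Segments the epidermis
    surface and dermis band, skeletonizes the dermal vessel network into a
    branch/junction graph, and computes 18 morphometric features at three
    scales of detail (micro, meso, macro). Tracks per-feature percentage
    changes across a post-occlusive reactive hyperemia (PORH) timeline,
    aggregates them per scale with group-difference statistics, derives a
    per-minute disease index by leave-one-subject-out feature-selected
    random-forest classification, and quantifies potential confounding with
    nested logistic models and a linear probability model. Includes a
    ground-truthed synthetic phantom generator (vessel trees, dual-band
    volumes, reactivity time series, feature-level cohorts) so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    RNifti,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
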