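Package: macropath
Title: 3D Pathomic Profiling of Tumor-Associated Macrophages in Lymph Nodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-associated macrophages (CD68+/CD163+) in
    three-dimensional fluorescence images of human lymph node tissue.
    Provides a seeded synthetic-data generator with diagnosis-specific
    presets, 3D segmentation and per-cell morphometry (volume, surface,
    sphericity, ellipticity, axis lengths, antigen density), unit-disk
    cell graphs with a data-driven edge radius and spectral/efficiency
    features (Estrada index, local communication efficiency), assembly of
    24-feature per-image pathomic profiles, feature-wise Mann-Whitney
    prototyping of neoplastic entities against a reactive baseline, and a
    repeated stratified-split bagged decision-tree diversity analysis with
    aggregated confusion matrices, averaged one-vs-rest ROC curves and
    permutation-based feature attribution.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    igraph,
    jsonlite,
    tiff,
    EBImage,
    randomForest,
    withr
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pROC,
    readxl,
    ggplot2
Config/testthat/edition: 3
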