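Package: cardiopatch
Title: Nucleus Segmentation, Patch Tiling and Patient-Level Classification
    for Cardiac Fluorescence Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for heart-failure diagnosis and left
    ventricular reverse remodeling prognosis from fluorescence microscopy of
    endomyocardial biopsies. Segments cell nuclei from DAPI-stained whole-slide
    images (grayscale conversion, bicubic enlargement, Otsu binarization,
    morphological-gradient contouring, connected-component labeling and area
    filtering), builds dual-stain composites from paired DAPI and gamma-H2A.X
    channels, tiles slides into fixed-size patches, constructs patient-exclusive
    train/test datasets with four-rotation augmentation, trains pluggable patch
    classifiers (a small vision transformer trained from scratch, and an
    intensity-feature logistic baseline), and aggregates patch predictions to
    patient-level labels by majority vote with full ROC/PR evaluation. Includes
    a seeded synthetic-slide generator with ground truth so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
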