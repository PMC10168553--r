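Package: lungcontour
Title: Contour-Based Lung Parenchyma Segmentation with Balanced
    Augmentation and Artificial Consolidations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Training-data engineering and evaluation pipeline for robust
    2D lung parenchyma segmentation on coronal MR-like images. Generates
    synthetic lung phantoms with ground-truth masks, converts masks into
    6-pixel closed contour labels, inserts artificially-generated
    consolidations (uniform fill, median filtering, Gaussian border
    blending), balances training sets across sequence/slice-position
    categories with integer augmentation factors, trains a compact U-Net
    contour classifier, reconstructs parenchyma masks by thresholding and
    flood-filling predicted contours, and scores segmentations with the
    Sorensen-Dice coefficient, Hausdorff distance and Welch t-tests with
    Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    RNifti,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
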