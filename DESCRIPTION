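Package: felmorph
Title: Digital Nuclear Morphometry for Breast Fibroepithelial Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for digital nuclear-morphometric analysis of
    H-DAB stained breast fibroepithelial lesion (FEL) sections: colour
    deconvolution of brightfield RGB tiles into hematoxylin and DAB optical
    densities, watershed segmentation of stromal nuclei with DAB-based
    exclusion of epithelial and leukocyte nuclei, six calibrated nuclear
    shape descriptors (area, perimeter, circularity, maximum and minimum
    caliper, eccentricity), per-case aggregation, logistic nuclear-morphology
    scores for fibroadenoma versus benign phyllodes tumour diagnosis and for
    phyllodes tumour grading, and the accompanying cohort statistics
    (Mann-Whitney comparisons, ROC with Youden cutoff selection, multivariate
    logistic model fitting, Kaplan-Meier and log-rank event-free-survival
    analysis). A synthetic-data module generates stained tiles with
    closed-form ellipse ground truth and feature cohorts with prescribed
    group means, so that every stage is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    MASS,
    stats,
    grDevices,
    survival,
    tiff,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
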