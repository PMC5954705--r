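Package: petrad
Title: PET Radiomic Texture Analysis and Predictor Screening for Thyroid Incidentalomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for [18F]FDG-PET texture
    analysis of thyroid incidentalomas: lesion segmentation at 40% of SUVmax,
    absolute 64-level gray-level quantization over 0-20 SUV, a radiomic
    feature bank spanning conventional SUV metrics, intensity-histogram,
    shape, and gray-level co-occurrence (GLCM), neighborhood difference
    (NGLDM/NGTDM), run-length (GLRLM) and zone-length (GLZLM) texture
    families, and a univariate predictor-screening workflow (one-way ANOVA,
    ROC/AUC pre-selection, mutual-correlation audit, Fisher-exact optimal
    dichotomization and truth-table predictive scores). A synthetic PET
    phantom generator produces cohorts with known class structure so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    RNifti,
    generics,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
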