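Package: petrad
Title: PET Radiomics Texture Features and Survival Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for FDG-PET radiomics survival analysis on
    synthetic data: spherical tumor phantoms with controllable border sharpness
    and noise, 40% SUVmax isocontour segmentation with a 2.6 ml volume filter,
    grey-level texture features (run-length, co-occurrence, size-zone,
    neighbourhood grey-tone difference and texture-spectrum codes) computed on
    64-bin min-max quantized volumes of interest, repeated-LASSO stability
    selection for penalized Cox models, and survival statistics (Cox
    regression, Harrell concordance index with cross-validation and paired
    bootstrap model comparison, Kaplan-Meier curves, rank-sum tests). All
    texture matrices are built from explicit definitions so that they can be
    verified against brute-force enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    igraph,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
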