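Package: fetradiomics
Title: Radiomics of Visually FET-Negative Gliomas from Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dynamic O-(2-[18F]fluoroethyl)-L-tyrosine
    (FET) PET of gliomas that show no visually increased tracer uptake.
    Builds early (5-15 min) and late (20-40 min) tumor-to-background ratio
    (TBR) images and voxel-wise time-to-peak (TTP) parametric maps from 4D
    dynamic volumes, extracts a 93-feature radiomic profile (18 first-order
    plus 75 gray-level texture features) from a tumor volume of interest and
    its mirrored contralateral background, screens features with paired
    Wilcoxon signed-rank tests, and discriminates tumor from healthy tissue
    with nested cross-validated L2-regularized logistic regression. Includes
    a seeded synthetic dynamic-PET phantom generator emulating isometabolic
    and photopenic glioma kinetics so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    glmnet,
    igraph,
    stats,
    utils,
    tools
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
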