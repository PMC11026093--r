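Package: gyralpeaks
Title: Cross-Species Analysis of Gyral Peaks on Cortical Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects gyral peaks (local height maxima of gyri, operationalized
    as sulc minima within a k-ring mesh neighborhood) on triangle cortical
    surface meshes, accumulates subject peaks into group count maps, extracts
    group-wise peak clusters by anisotropic smoothing and watershed flooding,
    matches clusters across species through a vertex correspondence map into
    species-shared and species-unique classes (Dice overlap or a 7 mm
    center-distance criterion), and compares the two classes on inter-subject
    consistency, anatomical features, nodal connectome metrics, atlas
    neighborhood diversity, and regional gene expression selected by
    L1-penalized regression with cross-validation. Includes a synthetic-data
    generator with planted ground truth so every stage is testable without
    neuroimaging downloads, plus GIFTI and plain-text surface/metric/label
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    Rcpp,
    xml2,
    yaml,
    methods,
    tools,
    stats,
    utils
Suggests:
    glmnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
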