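Package: arterymap
Title: Mapping the Superficial Facial Arteries from MR Angiography for
    Augmented-Reality Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for extracting the superficial arterial
    network of the face from time-of-flight MR angiography volumes and
    projecting it into a camera view anchored on 68 facial landmarks.
    Includes multiscale Hessian-based (Jerman) vessel enhancement, threshold
    segmentation restricted to the subcutaneous band between skin and skull,
    marching-cubes surface meshing with STL export, centerline extraction and
    landmark-region artery labeling, least-squares similarity registration and
    pinhole reprojection, the deviation and visualization-rate statistics used
    to evaluate projection accuracy, and a seeded synthetic phantom generator
    so that every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
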