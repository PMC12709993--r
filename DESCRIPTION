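Package: canoret
Title: Hybrid Radiative-Transfer and Deep-Learning Retrieval of Rice Canopy
    Water and Chlorophyll Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieves canopy chlorophyll content (CCC) and canopy equivalent
    water (CEW) of rice under water stress from top-view hyperspectral imagery
    and front-view RGB photographs. Couples a PROSPECT-5 leaf optical model
    with the 4SAIL canopy bidirectional reflectance model (Campbell ellipsoidal
    leaf-angle distribution, hot-spot parameter derived from leaf area, tiller
    number and canopy height, wet/dry soil mixing) to build Monte-Carlo
    look-up-tables, performs cost-function look-up-table inversion, screens
    drought-sensitive wavebands (per-band ANOVA with Tukey HSD, linear
    discriminant projection, Euclidean treatment gaps), extracts image
    phenotypes (EVI/NDVI plant-soil segmentation, mixed reflectance, Hough
    leaf-angle statistics, relative centroid height), and trains a small
    convolutional regression network that is pre-trained on simulated spectra
    and fine-tuned on measured-style spectra augmented with the image-derived
    phenotype vector. A synthetic-scene generator with full ground truth makes
    every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
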