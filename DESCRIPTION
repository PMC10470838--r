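Package: saltFCE
Title: Non-Destructive Salt-Tolerance Grading from Hyperspectral and LiDAR
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts computing phenotypic traits from calibrated
    hyperspectral reflectance cubes (16 narrow-band vegetation indices over a
    TVI-segmented canopy mask) and from canopy point clouds (grid plant
    height, occupied-cell canopy leaf area, convex-hull volume after a
    statistical-outlier / voxel / moving-least-squares filter chain), then
    grades samples with an entropy-weighted fuzzy comprehensive evaluation
    (FCE-E): min-max standardization, Shannon-entropy weights, trapezoidal
    grade memberships composed by the weighted-average operator, and
    maximum-membership rating on a four-grade scale. Includes a PCA
    first-component composite-score baseline, trait-statistics tables
    (coefficient of variation, entropy divergence, variance contribution),
    rating-consistency and rank-agreement comparisons, seeded synthetic
    generators for scenes, canopies and trait cohorts with known ground
    truth, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
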