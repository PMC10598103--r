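Package: segagree
Title: Interobserver Agreement Metrics for Radiotherapy Target Volumes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies interobserver agreement (IOA) between expert
    delineations of radiotherapy target volumes (GTV, ITV, PTV). Computes
    four complementary geometric metrics per observer pair -- the
    Dice-Sorensen coefficient, the symmetric Hausdorff distance in mm
    (anisotropic-spacing aware), the probabilistic distance, and the
    volumetric similarity, plus the Jaccard index -- over all observer
    pairs of a multi-observer cohort, and aggregates them into per-case
    and pooled min/max/mean/median/std summary tables. Includes readers
    and writers for voxel-mask volumes (NRRD) and planar contour structure
    sets with even-odd rasterization, and a seeded synthetic multi-observer
    cohort generator with tunable interobserver boundary noise for fully
    reproducible end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
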