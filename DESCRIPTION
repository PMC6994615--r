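Package: standseg
Title: Automatic Forest Stand Segmentation and Area-Based Inventory from
    Airborne LiDAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates forest stands from airborne LiDAR by rasterizing
    canopy height (85th percentile) and vegetation density at 4 m
    resolution, fusing them with a maximum-likelihood land-cover
    classification into a composite, and segmenting the composite with a
    gradient-seeded, limited iterative region-growing algorithm followed
    by multi-pass threshold merging. Estimates stand parameters (Lorey's
    mean height, quadratic mean DBH, basal area, stand volume) from
    plot-level LiDAR metrics with sparse Bayesian (relevance-vector)
    linear regression, validated by leave-one-out, and aggregates 20 m
    cell predictions to stand level. Includes a seeded synthetic-scene
    generator (stand mosaic, tree lists, point cloud, aerial image, field
    plots) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
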