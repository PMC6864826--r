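Package: cropgeobia
Title: Object-Based Plant Health Mapping from Multispectral Orthomosaics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Geographic object-based image analysis (GEOBIA) pipeline that turns a
    very-high-resolution 4-band (green, red, red-edge, near-infrared) crop
    orthomosaic into a per-seeding-point plant-health map. Provides mean-shift
    segmentation of the joint spatial-spectral domain (with a tiled large-scale
    mode), Gaussian maximum-likelihood classification of segment spectral modes
    into soil, shadow and five health levels, seeding-point localization by
    connected-component labeling and area-calibrated KMeans clustering, a
    disc-neighborhood health index per seeding point, NDVI computation,
    confusion-matrix evaluation, Amdahl's-law speedup utilities, and a synthetic
    row-crop scene generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
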