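Package: toothfea
Title: Plane-Strain Finite Element Biomechanics of Shark Tooth Outlines
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative biomechanics of two-dimensional tooth profiles.
    Generates parametric synthetic tooth outlines emulating otodontid
    ("megatooth" shark) heterodonty, triangulates them with a built-in
    constrained Delaunay mesher into linear (constant-strain) triangle
    meshes, solves plane-strain linear elasticity under puncture (apical
    point load) and draw (edge-distributed lateral load) scenarios with
    life-size or surface-area-scaled bite forces, summarises von Mises
    stress fields via mesh-weighted arithmetic means, and tests temporal
    trends in structural performance with age-resampled Pearson
    correlations that propagate chronostratigraphic uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
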