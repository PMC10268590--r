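Package: perisyn
Title: Perisynaptic Astrocyte Morphometry from Labeled EM Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies astrocytic engagement of individual synapses in 3D
    labeled electron-microscopy segmentation volumes. Provides PSD-anchored
    torus metrics (PSD volume, minimum PSD-to-astrocyte distance,
    perisynaptic astrocyte volume), cross-K style relational shape curves
    (volume, surface area, cut area, contour) measured over r-parallel
    dilations of the postsynaptic density with spherical-growth
    normalization, Monte Carlo permutation comparison of measurement curves
    between groups, and a synthetic tripartite-synapse phantom generator
    with analytic ground truth so that every stage of the pipeline can be
    validated without original EM data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
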