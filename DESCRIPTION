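Package: airwaymorph
Title: Automated Tracheobronchial Airway Morphometry from Micro-CT Casts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated pipeline for tracheobronchial airway morphometry
    from segmented micro-CT volumes of airway casts. Given a binary (or
    thresholded grayscale) volume with isotropic voxel spacing, the pipeline
    pre-processes the volume (threshold, resampling, morphological opening,
    component selection), extracts a centerline network by topology-preserving
    3D thinning, repairs network exceptions (closed loops, trifurcations,
    spurious nodes, spurs), and measures each branch: length, averaged
    hydraulic diameter from perpendicular cross-sections, branch angle,
    inclination to gravity, Raabe binary label and airway generation.
    A parametric voxel-phantom generator with analytic ground truth supports
    validation, and comparison statistics (through-origin regression, Pearson
    correlation, per-generation ANOVA, Bonferroni-corrected paired t tests)
    support method and strain comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
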