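Package: phosphenes
Title: Shape Analysis and Linear Summation of Electrically Elicited Phosphenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying phosphene drawings collected from epiretinal
    prosthesis users and for testing the axon map account of two-point
    perception. Converts binary touchscreen drawings into moment-based shape
    descriptors (area, perimeter, major/minor axis length, phosphene count),
    models retinal nerve-fiber-bundle trajectories to decompose inter-electrode
    separation into between-axon and along-axon components, implements the
    standard-pulse normalization and power-transform preprocessing pipeline,
    and provides the accompanying statistical battery (standardized regression
    with partial correlations, no-intercept summation regression, linear
    mixed-effects models, Welch tests from summary statistics, and AIC/BIC
    model comparison). A deterministic synthetic drawing generator emulates the
    statistical structure of such experiments so every pipeline stage can be
    exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    EBImage,
    png,
    yaml,
    lme4,
    lmerTest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'phosphenes-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'DrawingSet-methods.R'
    'RcppExports.R'
    'drawing-metrics.R'
    'retina-geometry.R'
    'synthetic-data.R'
    'io.R'
    'preprocessing.R'
    'stats-models.R'
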