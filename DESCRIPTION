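Package: pondsight
Title: Road-Viewshed Visibility and Classification-Tree Modelling of
    Invasive Fish in Agricultural Ponds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to score the visual exposure of agricultural ponds to
    surrounding roads with a cumulative viewshed analysis over a digital
    surface model, to compute landscape predictors (road density, urban
    ratio, graded river-density buffers, canal connectivity classes,
    trophic state), and to model invasive-fish presence with binary
    classification trees grown by Gini splitting, pruned by weakest-link
    cost-complexity pruning, and sized by repeated ten-fold
    cross-validation with the one-standard-error rule.  A seeded
    synthetic-landscape generator with planted presence rules makes the
    whole pipeline testable end to end without external GIS data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
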