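Package: flowparse
Title: Causal Separation of Self-Motion and Object Motion in Optic Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A feedforward, multi-layer model of optic-flow processing that
    separates retinal motion into its causal sources. Heading-likelihood
    residual surfaces are computed with the subspace algorithm for overlapping
    regions of the visual field; cross-shaped saddle-point operators turn each
    surface into an activity map whose maximum decides whether the surface
    informs heading estimation or the detection, localization and direction
    estimation of an independently moving object. Includes the dot-cloud
    self-motion simulation paradigm used to exercise the model end-to-end
    (scene construction, motion conditions, directional noise, hemifield
    removal) and performance metrics for heading error and bias, flow-parsing
    quality, object detection, localization error and relative tilt.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
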