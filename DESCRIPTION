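Package: smilevc
Title: Spatial Mixed Linear Effect Models for Family-Based Variance
    Components and Pollution Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of genetic, within-family environmental, and
    spatially correlated community-level variance components from nuclear-family
    binary phenotypes, using a linear mixed model on the observed scale with
    conditional (CAR) or simultaneous (SAR) autoregressive spatial random
    effects on a location adjacency graph. Includes liability-scale conversion
    of variance components, BIC-based selection among sub-models, best linear
    unbiased prediction of location effects, a two-stage instrumental-variable
    extension for causal inference of location-level exposures with wind speed
    and direction as instruments, and a synthetic-cohort simulator emulating
    nuclear families nested in locations on a spatial graph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
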