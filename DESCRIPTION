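Package: morphdrift
Title: Geometric Morphometrics and Multivariate Drift Tests for Temporal
    Samples
Version: 1.0.0
Authors@R:
    person("Rowan", "Merritt", email = "rowan.merritt@example.org",
           role = c("aut", "cre"))
Description: A pipeline from raw 3D skull landmarks to an
    evolutionary-mode verdict for two temporal samples of a single
    population.  Reads TPS and long-format CSV landmark files, imputes
    missing landmarks with a 3D thin-plate spline, merges dorsal and
    ventral digitizing views, performs generalized Procrustes
    superimposition with an object-symmetry decomposition, fits
    randomized-residual-permutation (RRPP) Procrustes ANCOVA models with
    Goodall's F, runs shape PCA, builds phenotypic variance-covariance
    (P) matrices from interlandmark distances, compares them with the
    random-skewers method, and tests observed divergence against the
    multivariate drift expectation MVN(0, P * t/Ne).  Includes fully
    seeded synthetic-data generators so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
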