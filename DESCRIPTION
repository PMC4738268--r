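Package: cscplasticity
Title: Two-Compartment Cancer Stem Cell Plasticity Modelling and Signature Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and exact-stochastic (Gillespie) simulation of a
    two-compartment cancer stem cell / non-stem cell interconversion model with a
    piecewise-constant dedifferentiation rate, an in-silico mammosphere formation
    assay, brute-force grid-search parameter estimation with tolerance-band
    acceptance, derivation of two-fold expression signatures with two-sided
    Fisher exact overlap testing, and synthetic-data generators emulating
    biomarker FACS time courses, mammosphere counts and expression matrices.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
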