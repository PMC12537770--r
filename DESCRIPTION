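Package: lvtrio
Title: Three-Species Lotka-Volterra Dynamics and Invasion Resistance of a
    Bacteria-Yeast Community
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the resistance of a two-species
    Escherichia coli-yeast co-culture to invasion by a third bacterial
    species. Provides logistic growth-curve fitting for plate-reader
    optical-density series, spent-media interaction metrics, a
    growth-rate-based predictor of pairwise competition outcomes, classic
    and frequency-dependent three-species Lotka-Volterra simulators with
    serial-transfer and delayed-invader protocols, extinction-threshold
    outcome classification, interaction-coefficient sweeps producing
    coexistence/exclusion phase diagrams, and generators of synthetic
    plate-reader, flow-cytometry and colony-count data for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
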