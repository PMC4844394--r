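Package: elicitCa
Title: Modeling and Analysis of Elicitor-Induced Cytosolic Calcium Transients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of elicitor-induced cytosolic calcium
    transients in plant cell cultures. Implements an adapted two-variable
    Li-Rinzel model of inositol-phosphate-gated calcium release from an
    internal store (channel, leak and pump fluxes with a slow inactivation
    gate), normalized stimulus protocols with a fitted transfer function
    linking stimulus amplitude to elicitor concentration, ratiometric
    aequorin luminescence-to-calcium calibration, a seeded synthetic-data
    generator emulating luminometer dose-response and double-elicitation
    experiments, and pipeline stages for feature extraction, dose-response
    and refractory-period analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
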