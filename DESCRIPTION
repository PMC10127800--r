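Package: fscvfit
Title: Kinetic Modelling and Fitting of Stimulated Dopamine FSCV Transients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates electrically evoked dopamine transients in the dorsal
    striatum as measured by fast-scan cyclic voltammetry (FSCV) at a
    carbon-fiber microelectrode, using a four-equation kinetic model:
    burst-stimulated release, Michaelis-Menten reuptake by the dopamine
    transporter, first-order electrode transfer, and reversible surface
    adsorption. Provides trace summary statistics (evoked peak amplitude,
    clearance half-time, goodness of fit), bounded nonlinear least-squares
    fitting of the model to recordings with a configurable free-parameter
    mask, seeded synthetic-cohort generation for wild-type and knockout
    genotypes, and a reproducible end-to-end experiment pipeline comparing
    fitted genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
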