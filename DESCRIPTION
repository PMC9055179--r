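Package: lipiddpd
Title: Dissipative Particle Dynamics of Asymmetric Phospholipid Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained dissipative particle dynamics (DPD) simulation of
    two phospholipid species in water, with a compiled cell-list engine
    (Groot-Warren thermostat and modified velocity-Verlet integrator),
    pre-assembled lamellar, cylindrical and spherical initial conditions,
    lowest-energy structure selection, and a full observable suite: per-species
    density profiles, second-Legendre orientational order, gyration tensors and
    shape factors, three-stage energy-trace segmentation, Irving-Kirkwood local
    pressure tensors, interface tension and osmotic-pressure profiles, and an
    automatic membrane/tube/vesicle morphology classifier for building phase
    diagrams over tail-chain lengths.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
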