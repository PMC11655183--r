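Package: bogflux
Title: Microform Source Attribution of Peatland CO2 Fluxes from Chamber and
    Eddy-Covariance Data
Version: 0.1.0
Authors@R: person("bogflux", "maintainers", email = "bogflux@example.org",
    role = c("aut", "cre"))
Description: Tools to attribute ecosystem-scale CO2 fluxes of rewetted bogs to
    their surface microforms (hummocks, hollows, near-tree variants) and an
    encroaching birch canopy. Computes quality-controlled CO2 fluxes from
    closed-chamber concentration traces (moving-window regression, minimal
    detectable flux, leaf-area normalised branch fluxes), fits campaign-wise
    Lloyd-Taylor respiration and rectangular-hyperbola light-response models
    per microform, reconstructs daily fluxes over a hydrological year, pairs
    areally upscaled chamber composites with eddy-covariance half-hours,
    partitions daily eddy-covariance GPP and ecosystem respiration into source
    contributions, and assembles annual carbon and greenhouse-gas balances
    with quadrature error propagation. Includes a synthetic-data generator
    emulating a contrasting open/tree-encroached site pair so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
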