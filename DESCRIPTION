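Package: reefdiss
Title: Coral-Skeleton Dissolution and Reef Accretion Under Ocean Acidification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for passive-dissolution experiments on coral
    skeletons and a vertical reef-growth model under ocean acidification.
    Provides unit-checked conversion between areal calcium-carbonate mass
    fluxes and vertical reef-framework rates, group comparisons and an
    exponential surface-area-dissolution fit for dissolution-experiment
    tables, semi-empirical and parametric sea-level projections for IPCC
    emission scenarios, a fixed-step Runge-Kutta accretion-dissolution model,
    keep-up diagnostics against sea-level rise, and a seeded synthetic-data
    generator emulating the experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
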