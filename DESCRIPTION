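Package: palmghg
Title: Measurement-Based Greenhouse-Gas Budgets and Life-Cycle Assessment of
    Palm-Oil Biodiesel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn ecosystem flux measurements from oil palm
    plantations into annual greenhouse-gas budgets and per-MJ life-cycle
    assessments (LCA) of palm-oil biodiesel. Includes diurnal gap-filling and
    annual integration of half-hourly net ecosystem exchange (NEE), trapezoidal
    annualization of static-chamber soil CO2/CH4/N2O fluxes, net ecosystem
    productivity and net global warming potential budgets, calibration of a
    soil-carbon decay curve after forest conversion, construction of
    rotation-cycle management scenarios, an LCA engine with energy allocation
    and land-use-change accounting, and Monte Carlo uncertainty propagation
    with pedigree-matrix data-quality factors. A synthetic-data generator
    emulates the statistical structure of eddy-covariance and chamber
    measurements so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
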