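Package: ggflux
Title: Constraint-Based Analysis of Glucosylglycerol Salvage in Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the re-assimilation of the osmolyte glucosylglycerol
    (GG) in Synechocystis with constraint-based (flux balance) modelling.
    Represents stoichiometric models (BiGG-style JSON and SBML Level 3 fbc),
    extends a base reconstruction with the GG transport, degradation and
    storage reactions, simulates knockout strains, computes biomass-maximum
    fitness ratios under measured GG uptake fluxes, compares hydrolytic and
    phosphorolytic cleavage, and estimates growth rates and specific GG
    consumption rates from batch-culture optical density and glycerol
    time series. Ships a small photoautotrophic toy model with hand-derivable
    optima and a seeded culture simulator so the whole pipeline runs offline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
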