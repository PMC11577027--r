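Package: soilflux
Title: Energy-Flux Analysis of Soil Food Webs in Nested Mesocosm Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for food-web energetics of soil fauna communities sampled in
    blocked, nested mesocosm experiments. Builds per-mesocosm communities from
    raw faunal sample records (length-mass regressions, core-area and
    fresh/dry-soil abundance scaling), constructs column-stochastic trophic
    preference matrices from diet fractions refined by predator-prey mass
    ratios, prey agility, defenses, vertical stratification and relative prey
    biomass, solves the steady-state energy-flux balance with resource-specific
    assimilation efficiencies, decomposes total flux into predation, herbivory,
    microbivory and detritivory, computes community biomass, community-weighted
    mean body mass and Shannon-exponent diversity, and estimates treatment
    contrasts and flux-structure slopes with a hierarchical bootstrap that
    respects block/EcoUnit nesting. Includes a synthetic-experiment generator
    with configurable treatment effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
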