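Package: swinecon
Title: Welfare Economics of Replacing Invasive Piglet Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Farm-level and market-level economic analysis of replacing
    invasive piglet husbandry procedures (surgical castration, tail
    docking, teeth clipping) with welfare-friendly management
    (immunocastration plus environmental enrichment). Provides a
    synthetic herd generator with group-specific slaughter-weight and
    mortality distributions, production summary statistics (weight
    moments, mortality rates, odds ratios, back-derivation of standard
    deviations from printed confidence intervals), an itemized and
    headline per-head/per-kg cost model, fixed-price farm profit
    comparison, an elasticity-calibrated linear partial-equilibrium
    model of the US pork market with supply shift and consumer/producer
    surplus accounting, an elasticity sensitivity grid, and an
    empirical (basic) bootstrap for confidence intervals on all
    economic outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
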