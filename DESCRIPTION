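Package: metacrate
Title: Crossover Metabolism-Crate Trial Analysis for Ruminant Water and
    Nitrogen Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing two-diet crossover metabolism-crate
    trials in ruminants: intake and digestibility bookkeeping from
    offered/refused herbage, liquid-phase digesta kinetics from pulse-dosed
    CoEDTA fecal marker curves (one-compartment models with delay), daily
    water and nitrogen mass-balance budgets, classical 2x2 crossover diet
    contrasts, regression-based partitioning of nitrogen excretion with BIC
    model selection, and translation of urinary-nitrogen outcomes into
    urine-patch loading and relative nitrate-leaching change. Includes a
    synthetic-trial generator reproducing the statistical structure of such
    trials so every analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
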