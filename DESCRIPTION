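Package: netpharm
Title: Network Pharmacology Component Optimisation for Herbal Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative network pharmacology
    of multi-herb formulas. Screens compounds by the Lipinski rule of five,
    builds a weighted disease-gene regulatory network and a bipartite
    compound-target network, solves a deviation-variable goal program to
    delimit the function response space (FRS) and its effective proteins,
    extracts a key group of effective components (KGEC) with a genetic
    0/1-knapsack algorithm, and validates selections with hypergeometric
    over-representation analysis and pathway-coverage statistics. Includes
    seeded synthetic-data generators with planted ground truth so every stage
    is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    igraph,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
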