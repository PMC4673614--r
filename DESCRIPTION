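Package: tumorgame
Title: Agent-Based Game Model of Avascular Tumor Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates avascular tumor growth on a two-dimensional lattice with
    an agent-based composite model: nutrient reaction-diffusion with
    fixed-concentration boundaries, extracellular-matrix degradation by living
    cells, necrosis below a nutrient threshold, and game-theoretic coupling
    between proliferative and invasive phenotypes through a payoff matrix.
    Provides morphometric statistics of the growing colony (phenotype counts
    and fractions, angular front profiles, radial growth velocity, per-sector
    radial distribution functions, global surface roughness and its velocity),
    a payoff-sweep experiment driver with deterministic per-trial seeding and
    resume support, tidy accessors and ggplot2 visualisations, and a
    command-line interface for running and summarising simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
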