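Package: colonymh
Title: Metaheuristics as Synthetic Circuits in Growing Bacterial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Runs metaheuristic searches (a Simple Genetic Algorithm and
    Simulated Annealing) inside an agent-based simulation of a growing
    bacterial colony, where candidate solutions are plasmid-presence bit
    strings, crossover is bacterial conjugation, mutation acts on promoters
    at division, and the annealing temperature is a diffusing, degrading
    environmental signal (aTc). Fitness is a three-tier repressor cascade
    (araC/trpR -> lacI/cI -> GFP) compiled from a {1,0,x} protein-presence
    pattern, with the Boolean satisfiability problem encoded one clause per
    conjugative plasmid. The package also provides the classical fixed-pool
    bit-string versions of both algorithms for head-to-head generation
    counts, a quorum-sensing Game-of-Life cellular automaton driven by a
    band-detector rule, a reaction-diffusion signal grid, and an interpreter
    that turns a flat parameter file into a runnable simulation
    configuration and a gro-style skeleton specification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    Matrix,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
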