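Package: rwsim
Title: Spatial Monte Carlo Simulation of Circular Genomes and Ribozymes in the Precellular RNA World
Version: 0.1.0
Description: A seeded, observable Monte Carlo simulator of the earliest
    (precellular, "naked") stage of the RNA world, in which circular RNA
    genomes and linear ribozymes divide the labour of heredity and function
    on a toroidal lattice. Molecules -- nucleotide precursors, nucleotides,
    linear and circular RNA strands, and template/substrate complexes --
    inhabit the rooms of an N x N grid and undergo template-directed
    replication, random and end-to-end ligation, bond breaking, end decay and
    diffusion with configurable per-event probabilities. The package provides
    validated parameter sets, declarative scenario configurations with
    inoculation schedules and timed species-scoped parameter interventions,
    named presets for the canonical one-gene spread, noncoding-sequence
    emergence and two-gene takeover experiments, sequence-level species
    census tools, tidy time-series and spatial-snapshot outputs, ggplot2
    visualisation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
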