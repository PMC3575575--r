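Package: SRBranching
Title: Self-Regulating Branching Processes with Mutation and Their
    Embedded Deterministic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of one-type and multitype
    self-regulating (density-dependent) branching processes in which
    each individual produces a Poisson number of offspring, offspring
    may mutate among genotypes according to a row-stochastic mutation
    probability matrix, and offspring survive to reproduce with a
    Weibull probability that decreases with total population size.
    Provides exact aggregated samplers based on Poisson superposition
    and splitting, the embedded deterministic difference-equation
    models obtained by iterating conditional expectations, fixed-point
    location, stability classification and empirical period detection
    for the one-type map, a reproducible Monte Carlo ensemble engine
    with per-replicate seed substreams, quantile-trajectory summaries,
    and tools for comparing deterministic predictions with the
    stochastic process, including a preset three-genotype
    mutation-selection experiment in which the two disagree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'onetype.R'
    'multitype.R'
    'deterministic.R'
    'ensemble.R'
    'io.R'
    'section5.R'
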