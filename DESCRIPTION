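Package: fadsim
Title: Individual-Based Simulation of Fitness-Associated Dispersal Evolution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-time, individual-based simulator for the evolution of
    fitness-associated dispersal (FAD) in structured populations. Diploid
    hermaphrodites carrying many bi-allelic deleterious-mutation loci and a
    dispersal-modifier locus live in island-model demes with a maximum
    capacity; each discrete generation consists of dispersal (uniform or
    fitness-ranked, with a survival cost), within-deme random mating without
    selfing, mutation, free recombination, and viability selection. The
    package provides the full lifecycle engine (implemented in C++ for
    speed), deme bookkeeping, steady-state (mutation-selection balance) and
    modifier-invasion experiment protocols, exact binomial invasion tests,
    takeover-time measurement, factorial parameter sweeps, configuration
    handling, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
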