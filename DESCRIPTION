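Package: autopoiesim
Title: Off-Lattice Particle Simulation of Autocatalytic and Autopoietic
    Chemistries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional, off-lattice, bead-spring particle
    simulator of a minimal artificial chemistry in which gamma-particles
    catalyse the synthesis of beta-particles from an alpha-particle food
    substrate and dendritic bonded networks self-assemble, reproduce by
    fragmentation, and decay. Physics combines a correlated random-walk
    (Brownian) force, ideal linear bond springs, three-body torsion
    springs, soft-sphere collisions, and linear drag in a sealed cubic
    container. Stochastic reaction mechanisms (beta synthesis, gamma
    splitting, bond addition and insertion, and decay) run per timestep
    with tabulated, neighbour-count-dependent probabilities. Bonded
    connected components are identified as individual instances, and
    per-second observables (instance counts by majority colour, sizes,
    species mass totals, and mean colour values) quantify how suppressing
    bonding pathways turns one collective autocatalytic entity into many
    boundary-free self-producing individuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
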