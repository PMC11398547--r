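Package: polyfock
Title: Fock-Space Rule-Based Modeling of Multi-Particle Complexes
Version: 0.1.0
Authors@R:
    person("polyfock", "maintainers", email = "polyfock@example.org",
           role = c("aut", "cre"))
Description: Simulator and analytics toolkit for rule-based models of
    macromolecular complexes built on a hard-core boson Fock space. Particles,
    binding sites and bonds are excitation modes; reaction rules are products
    of creation, annihilation, presence and absence operators. The package
    provides exact microstate master-equation propagation, a Gillespie
    stochastic simulation algorithm driven by operator eligibility, a species
    census of trajectories via canonical labeling of complex topologies,
    closed-form equilibrium partition-function analytics for polymer systems
    (directed, isotropic and branched homopolymers), and a brute-force Wick
    contraction engine that verifies the factory/gallery equivalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
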