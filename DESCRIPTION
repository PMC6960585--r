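Package: ringmix
Title: Coarse-Grained Molecular Dynamics of Semiflexible Ring-Polymer
    Mixtures in Spherical Confinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, simulates and analyses binary mixtures of semiflexible
    ring (and linear) bead-spring polymers confined in a hard sphere or a
    periodic box. Chains interact through FENE bonds, a purely repulsive
    shifted-truncated Lennard-Jones (WCA) pair potential and a cosine bending
    potential, and are integrated in the NVT ensemble with a velocity-Verlet
    Nose-Hoover scheme. The builder generates unknotted, mutually unlinked
    initial states verified by Gauss linking numbers. Analysis functions
    compute the observables that characterise entropy-driven segregation of
    long stiff rings to the cavity wall: radial monomer density profiles,
    nematic-like ring orientation order, tangential/radial velocity
    decomposition of ring centres of mass, radial potentials of mean force,
    and the bending-energy/entropy decomposition against a bulk reference.
    A synthetic-fixture generator provides idealised configurations (rigid
    rings, Hopf links, Boltzmann radial samples) so every analysis stage is
    testable without long simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
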