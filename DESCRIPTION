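Package: actinotrap
Title: Particle-Based Simulation of Living Actin Filament Bundles in an
    Optical Trap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained molecular simulation of a bundle of grafted,
    living (polymerizing and depolymerizing) semi-flexible actin-like
    filaments pressing against a mobile, harmonically loaded wall, in a
    reactive grand-canonical ensemble.  Monomers and the wall follow
    Langevin dynamics integrated with a stochastic velocity-Verlet scheme;
    single-monomer (de)polymerization steps at the filament tips and
    grand-canonical exchange with a free-monomer reservoir are performed
    as Poisson-clocked Monte Carlo moves satisfying detailed balance.
    Includes the rigid-filament (Hill/Brownian-ratchet) analytic reference
    theory and an observable suite: wall-position distributions,
    relative-size-resolved reaction rates, autocorrelation functions with
    exponential fits, and equilibrium summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
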