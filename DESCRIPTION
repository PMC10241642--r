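Package: spherulite
Title: Optics of Birefringent Nanosphere Photonic Glasses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the brilliant-white optics of dense, disordered
    assemblies of radially anisotropic (spherulitic) nanospheres. Provides
    Mie scattering for spheres with distinct tangential and radial
    refractive indices, inference of the tangential index from resonance
    peak positions, a Langevin-dynamics generator of polydisperse photonic
    glass packings with a smoothed 12-0 soft-core pair potential,
    structural observables (pair correlation, structure factor,
    Percus-Yevick), a dependent-scattering transport model of slab
    reflectance, and a coupled-dipole solver for near-field coupling
    between pairs of birefringent spheres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
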