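Package: spheredl
Title: Spherical Electric Double Layers in the Solvent Primitive Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density functional theory and canonical Monte Carlo engines for the
    spherical electric double layer formed by a mixed, fully size- and
    charge-asymmetric electrolyte around a charged colloidal macroion, with the
    solvent treated as an explicit neutral hard-sphere component (solvent
    primitive model).  The density functional combines a Denton-Ashcroft
    weighted-density approximation for hard-sphere correlations with a
    perturbative electrostatic term built on mean spherical approximation
    direct correlation functions; the simulator is a Metropolis Monte Carlo
    sampler with Ewald electrostatics.  Includes a nonlinear Poisson-Boltzmann
    reference solver with species-specific distances of closest approach and
    derived double-layer observables: mean electrostatic potential, integrated
    charge, charge-reversal diagnostics and the capacitive compactness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
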