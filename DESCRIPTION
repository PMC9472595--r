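Package: tubulemc
Title: Kinetic Monte Carlo Simulation of Self-Limited Helical Tubule Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grand-canonical kinetic Monte Carlo simulation of triangular
    monomers assembling into helical tubules, together with the equilibrium
    (discrete lattice, Helfrich continuum, and Einstein-solid thermodynamic
    integration) and stochastic growth-closure kinetic models that predict the
    polymorphic (m,n) geometry distribution of the assembled tubules. Includes
    tubule lattice geometry utilities (chiral rollup indices, ideal dihedral
    angles, mesh construction), structure classification (defect-free,
    defective, open), ensemble aggregation, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
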