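Package: osmobalance
Title: Osmotic Force Balance Analysis of Aqueous Electrolyte Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing osmotic force balance simulations of
    aqueous electrolytes. Fits a modified Debye-Huckel free-energy model
    to z-binned salt concentration profiles obtained under a harmonic
    restraint, evaluates osmotic pressures and water activities along
    constant water-chemical-potential (molar) and constant-pressure
    (molal) thermodynamic routes, converts solution densities between the
    two ensembles, estimates partial molar volumes, and applies the
    chi-scaling scheme for Lennard-Jones cation-anion cross interactions.
    Includes synthetic-data generators (noisy binned profiles, an ideal
    restrained-solute Metropolis sampler, osmotic-coefficient tables) so
    the full pipeline can be exercised without molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
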