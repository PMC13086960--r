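Package: waxpore
Title: Model Building and Trajectory Analysis for Surfactant Transport
    Through Plant Epicuticular Wax Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building atomistic models of crystalline plant
    epicuticular wax slabs with nanometer-scale pores and carboxylate
    surface functionalization, composing surfactant/active-ingredient
    solutions at a target surface excess with full charge bookkeeping,
    generating synthetic labeled trajectories with known penetration
    kinetics and water-cluster structure, computing trajectory-derived
    observables (deepest-water penetration depth, pore occupancy, density
    scans, in-pore net charge, discrete water clusters), fitting
    exponential-saturation foliar-uptake kinetics to penetration traces,
    and post-processing one- and two-dimensional free-energy profiles
    (adsorption free energies, penetration barriers, ideal two-molecule
    reference surfaces, and convergence root-mean-square deviations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
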