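Package: dpdchem
Title: Chemistry-Derived Dissipative Particle Dynamics Parameters and
    Surfactant Self-Assembly Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Translates coarse-grained chemical structure into dissipative
    particle dynamics (DPD) force-field parameters and simulates surfactant
    self-assembly in water. Bead fragments are described by surface site
    interaction points (SSIPs); a liquid-phase speciation model converts SSIP
    descriptions into bead transfer free energies, which yield pairwise
    repulsion parameters through a volume-weighted combination rule. Harmonic
    bond rest lengths are calibrated in closed form so that simulated bond
    lengths match atomistic target distances despite the soft nonbonded
    repulsion acting between bonded beads. A compact DPD engine (soft
    conservative forces, pairwise thermostat, cell lists, velocity Verlet)
    and a micelle-analysis toolchain (aggregate clustering, aggregation-number
    distributions, critical micelle concentration, gyration-tensor shape
    classification) complete the pipeline from bead library to self-assembly
    observables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
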