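Package: ifesim
Title: Agent-Based Simulation of Interfollicular Epidermal Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Center-based, off-lattice simulator of interfollicular epidermis
    homeostasis. Cells are overdamped spheres interacting through short-range
    repulsive pair potentials above an immobile, undulated basal-membrane
    particle monolayer. Stem cells are bound to the membrane by a harmonic
    anchor, committed progenitors by a quartic anchor with a finite detachment
    threshold; division follows a deterministic cell-cycle phase plus a Poisson
    waiting time and is resolved by a growing elastic dumbbell; suprabasal
    cells differentiate under a calcium-coupled clock, cornify at a threshold,
    and desquamate from the tissue surface. Includes the perturbation pipeline
    that weakens progenitor-membrane adhesion and measures the transient
    thickening and recovery of the tissue, with ensemble averaging, turnover
    calibration, and division-axis statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
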