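Package: dipolescan
Title: Transition-State Macrodipole Stabilization Scans for Enzyme Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-residue transition-state stabilization analysis for rational
    enzyme engineering. Implements the ddE ledger (barrier shift upon deleting
    each environment residue from the electrostatic embedding), a classical
    point-charge Coulomb surrogate of the deletion experiment, eligibility
    selection around the QM region, candidate filtering with charge-cancelling
    mutation suggestions, geometry-stability analyses (Kabsch superposition
    RMSD, catalytic-distance monitoring over multi-model trajectories), and a
    synthetic toy-enzyme generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
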