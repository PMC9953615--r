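Package: flipscape
Title: Coarse-Grained Free-Energy Landscapes for Lipid Flippases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained free-energy modelling of P4-ATPase-style
    membrane transporters. Maps all-atom structures to a side-chain
    interaction-centre representation, builds an implicit membrane grid,
    estimates in-protein pKas and average ionization states by Metropolis
    Monte-Carlo proton transfer, assembles an ionization-aware folding
    free energy with per-residue decomposition, computes
    ligand-binding free energies by a linear-response scheme with a
    scaled van der Waals term, generates targeted-morphing
    conformational pathways between two end states, and couples the
    conformational profile with per-position lipid binding energies
    into a two-dimensional landscape with least-energy (minimax) path
    and barrier extraction. Includes deterministic synthetic generators
    for transmembrane helix bundles, two-state conformational pairs and
    toy lipids used throughout the test-suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
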