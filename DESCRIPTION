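Package: nanoadsorb
Title: Protein Adsorption and Denaturation Analysis on 2D Nanosheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds engine-ready 2H-MoS2 monolayer patches with a configurable
    nonbonded parameter model, assembles protein-on-sheet systems at a
    prescribed gap, and computes the structural and energetic observables used
    to characterise protein adsorption and denaturation on two-dimensional
    nanomaterials: heavy-atom contact counts, native-contact fraction Q(t),
    dihedral-based alpha-helix and hydrogen-bond ratios, salt-bridge and
    cation-pi detectors, Lennard-Jones and Coulomb protein-sheet interaction
    energies with per-residue decomposition and tail averaging, first
    solvation shell hydration counts, dewetting-slab water counts, and
    anchoring kinetics. A deterministic synthetic-trajectory generator with
    exact ground truth makes every analysis stage testable without running
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
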