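Package: chitinsmfs
Title: Single-Molecule Elasticity and Conformation Analysis of Chitin Across pH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pH-dependent single-molecule mechanics of
    chitin. Implements the freely jointed chain (FJC) and two-state
    quantum-mechanics-corrected FJC (TSQM-FJC) force-extension models,
    normalization and segmentation of AFM force spectroscopy retraction
    curves, ensemble fitting of the per-unit water-bridge free energy,
    and conformational metrics over molecular frames: radius of gyration,
    end-to-end distance, characteristic viscosity, and geometric
    intra-/intermolecular hydrogen-bond counting. A synthetic-data module
    generates force-extension ensembles and solvated single-chain frames
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
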