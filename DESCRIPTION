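Package: fragbind
Title: Per-Residue Protein-Ligand Interaction Energies by Conjugate-Cap
    Fragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes a protein-ligand binding energy into per-residue
    contributions with the molecular fractionation with conjugate caps
    (MFCC) scheme: each pocket residue is cut out of the chain, capped
    with its two neighbouring residues, and its ligand interaction energy
    is assembled from four capped-fragment energies so that cap
    contributions cancel.  Includes an incremental-radius binding-pocket
    convergence scan at several dielectric constants, a classical
    Coulomb/Lennard-Jones energy backend plus a file-based adapter for
    external quantum-chemistry codes, conceptual-DFT reactivity
    descriptors from frontier-orbital energies, a weighted docking-score
    combination, and a synthetic complex generator with ground-truth
    energetics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
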