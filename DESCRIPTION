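Package: AtomEnsembles
Title: Atomistic Conformational Ensembles by Equivariant Graph Denoising
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for generating and scoring atomistic
    conformational ensembles of proteins and small molecules with an
    SE(3)-equivariant iterative graph denoising network. Molecular systems
    are represented as atom-level chemical graphs with bond-separation and
    chirality annotations; stochastic corruption schemes define the
    denoising task for training and the initialization for docking-style
    inference. Includes the all-atom frame-aligned point error (FAPE),
    bonded-geometry and all-atom lDDT structural metrics, per-atom
    confidence (sigma) with pRMSD aggregation for model ranking,
    symmetry-aware ligand RMSD, active-site preorganization scoring, and a
    synthetic-fixture generator providing exact ground-truth systems for
    training and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
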