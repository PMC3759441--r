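Package: rmrscore
Title: Knowledge-Based Scoring and Essential Dynamics for Ligand-Bound
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("rmrscore", "authors", email = "rmrscore@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for ligand-bound protein conformational
    ensembles such as those produced by molecular dynamics simulations of
    cytochrome P450 enzymes.  Builds a distance-binned, mean-reference-state
    knowledge-based pair potential from a database of intermolecular contact
    distances, scores every frame of a multi-model PDB ensemble against it
    (total, per-pair and per-residue decompositions), and selects the most
    native-like frame.  Also provides Kabsch superposition and RMSD series,
    C-alpha covariance principal component analysis with porcupine-arrow
    export, binding-pocket selection, reactive-pair distance annotation with
    a catalytic-feasibility threshold, geometric hydrogen-bond detection,
    substrate-recognition-site classification of pocket residues, and fully
    seeded synthetic-data generators (contact databases, labelled pose
    ensembles, trajectories with planted collective modes) so the whole
    pipeline can be exercised without external structural databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
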