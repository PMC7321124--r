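Package: DockSelect
Title: Rational Docking-Protocol Selection from Pocket Voxels and Ligand
    Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts, for a protein binding pocket and a small-molecule
    ligand, how well each of a registry of molecular docking protocols will
    reproduce the crystallographic pose, and recommends the best protocol
    per complex. The pocket is voxelized into an eight-channel pharmacophore
    occupancy grid, the ligand is encoded as a hashed circular fingerprint
    plus physicochemical descriptors, and a two-legged multi-task network
    (3D convolutions for the pocket, fully connected layers for the ligand)
    regresses three self-docking quality statistics per protocol: the
    minimum and average pose RMSD and the number of poses below the crystal
    resolution. Includes four cross-validation split constructors (random,
    ligand-scaffold, protein-family, balanced protein-family), evaluation
    and protocol-selection statistics, and a synthetic benchmark generator
    so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    bio3d,
    ChemmineR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
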