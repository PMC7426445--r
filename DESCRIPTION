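Package: plastens
Title: Surface Plasticity and Flexibility Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies and localizes conformational flexibility and surface
    plasticity of protein ensembles. Computes per-voxel occupancy mean and
    standard deviation grids with Gaussian smoothing to measure surface
    plasticity, average-linkage RMSD clustering of trajectory frames with a
    distance cutoff, 2D-RMSD matrices, RMSF and crystallographic B-factors,
    psi-torsion features, and a minimal tICA / Markov-state-model kinetics
    stack, so that two ensembles (for example a naive versus an
    affinity-matured antibody fragment) can be compared for rigidification.
    Includes multi-model PDB and OpenDX grid I/O and a synthetic-ensemble
    generator with known flexibility and kinetic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
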