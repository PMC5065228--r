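Package: sitedock
Title: Binding-Site Assignment of Docked Ligand Poses and Trajectory
    Distance Analysis for ABC Transporter Models
Version: 0.1.0
Authors@R:
    person("sitedock", "developers", email = "sitedock@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural analysis layer of membrane-transporter
    modelling studies: reading multi-model PDB structures and AutoDock
    Vina PDBQT pose files, residue-contact detection and assignment of
    docked ligand poses to named binding sites, normalized site-occupancy
    statistics for substrate versus non-substrate ligand cohorts, C-alpha
    distance and RMSD time-series analysis of molecular dynamics
    trajectories with block-average smoothing, global pairwise sequence
    alignment with identity/similarity statistics, CRAC cholesterol-motif
    scanning, membrane-depth annotation, and a deterministic synthetic-data
    generator so every stage of the pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
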