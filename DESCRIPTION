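Package: dimertraj
Title: Interface, Clustering and Formation-Energy Analysis of GPCR Dimer
    Molecular-Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse molecular-dynamics trajectories of G
    protein-coupled receptor (GPCR) homo- and hetero-dimers stored as
    multi-model PDB files. Provides Kabsch superposition with per-frame
    RMSD and per-residue RMSF profiles, geometric detection of inter-chain
    hydrogen bonds, salt bridges, pi-pi and cation-pi contacts with
    occupancy filtering across replicas, Gromos (Daura-type) conformational
    clustering with medoid extraction, a transparent Coulomb plus
    Lennard-Jones nonbonded model for chain-environment energy
    decomposition and the dimer formation energy balance, Ballesteros-
    Weinstein residue numbering for interface reporting, a seeded synthetic
    trajectory generator with planted ground truth, and a deterministic
    end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
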