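Package: idpkit
Title: Conformational Ensemble Analysis for Intrinsically Disordered
    Peptide Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of conformational ensembles of intrinsically
    disordered peptides from multi-model PDB trajectories, with emphasis
    on metal-ligand/amyloid-beta adducts sampled by replica-exchange
    molecular dynamics. Provides trajectory I/O and atom selections,
    Kabsch superposition with RMSD/RMSF statistics, gyration-tensor shape
    descriptors, a from-scratch Kabsch-Sander (DSSP) secondary-structure
    assignment, hydrogen-bond/salt-bridge/pi-stacking detection with
    occupancy tables, Calpha contact maps, Ramachandran analysis,
    density-based (DBSCAN) clustering on pairwise backbone RMSD, and
    replica-exchange ladder/acceptance utilities. A deterministic
    synthetic-conformer generator builds idealized peptides and a planar
    phenanthroline ligand from internal coordinates so that every
    analysis stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
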