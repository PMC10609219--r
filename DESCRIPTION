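Package: ifpr
Title: Direct Protein-Ligand Interaction Fingerprints from Structures and
    MD Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue protein-ligand interaction fingerprints
    directly from complex structure files (PDB, Tripos MOL2, PDBQT),
    including multi-MODEL snapshot series exported from molecular dynamics
    trajectories. Seven geometric detectors (hydrophobic contact,
    face-to-face and edge-to-face aromatic stacking, hydrogen bond with the
    protein as donor or acceptor, and ionic interaction with the protein as
    cation or anion) are evaluated for every binding-site residue in every
    frame and aggregated into interaction-hotspot occupancy tables.
    Companion tools provide Kabsch superposition, backbone and
    ligand-movement RMSD traces with a binding-stability classifier,
    docking-pose RMSD, enzyme-assay inhibition arithmetic with IC50
    estimation from log-linear regression, and a synthetic-complex
    generator for controlled interaction geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
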