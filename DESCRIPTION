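Package: carbscan
Title: Active-Site Analysis and Virtual Glycine Scanning for Carborane
    Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein complexes of icosahedral carborane
    ligands, built around the carbonic anhydrase II / IX active site.
    Reads and writes PDB and mmCIF coordinate files, performs Kabsch
    least-squares superposition with per-residue deviation analysis,
    enumerates and classifies protein-ligand and zinc-ligand contacts,
    detects boron-cluster dihydrogen bonds, grafts a ligand from a solved
    complex into a homologous active site, relaxes binding sites with the
    FIRE minimizer under a classical fixed-charge nonbonded model, and
    quantifies per-residue side-chain contributions to binding by a
    virtual glycine scan. Ships a deterministic synthetic-fixture
    generator so every stage can be validated against constructed ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
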