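Package: qmscreen
Title: Semi-Empirical Quantum-Mechanical Rescoring of Docked Ligand Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rescoring pipeline for high-throughput docking hit lists using
    semi-empirical quantum-mechanical single-point energies. Builds a reduced
    (hydrogen-capped) binding-site cluster around a docked pose library,
    evaluates single-point energies through a pluggable backend (a built-in
    deterministic classical toy potential, or a file-dialect adapter for an
    external PM7+COSMO engine), estimates ligand conformational entropy from
    rotatable-bond counts or Monte-Carlo torsional sampling, assembles four
    score variants (with or without complex relaxation and explicit
    protein/ligand deformation penalties), and evaluates screening power with
    enrichment factors, ROC curves and AUC. Includes generators for synthetic
    pockets and ligand/decoy libraries so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
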