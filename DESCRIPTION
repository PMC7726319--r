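Package: hetscreen
Title: Virtual-Screening Funnel and Biophysical Binding Analysis for
    Protein-Protein Interaction Inhibitor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational arm of a protein-protein
    interaction inhibitor discovery campaign: post-docking pose filtering
    against anchor residues, construction and validation (ROC/AUC) of
    tolerance-sphere pharmacophore models from aligned actives, binary
    linear-path fingerprints with Tanimoto average-linkage clustering and
    maximum common substructure extraction, NMR chemical-shift-perturbation
    analysis with quadratic single-site isotherm Kd fitting, antagonist
    induced dissociation (AIDA) metrics, ambiguous-restraint generation
    with Shrake-Rupley solvent accessibility, and Hill/isotherm fitting of
    microscale thermophoresis binding and competition curves.  Synthetic
    data generators with recorded ground truth make every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    bio3d,
    ape,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
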