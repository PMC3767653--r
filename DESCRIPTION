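Package: procleave
Title: Proteasomal Cleavage Site Prediction with VHSE Descriptors and
    Support Vector Machines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts proteasomal cleavage sites in protein sequences from
    the physicochemical context of the scissile bond. Residue windows
    flanking candidate cleavage sites are encoded with VHSE descriptors
    (principal component score vectors of hydrophobic, steric, and
    electronic amino acid properties), scaled to the unit interval, and
    classified with soft-margin support vector machines (linear or RBF
    kernel) whose hyperparameters are chosen by stratified 10-fold
    cross-validation. The per-position weight coefficients of the linear
    model are exposed as interpretable cleavage-specificity profiles, with
    derived favored/unfavored residue rankings and site favorability
    scores. Includes a corpus builder that turns MHC class I ligand or in
    vitro digest records plus source proteins into labeled
    cleavage/non-cleavage window samples, evaluation measures (accuracy,
    sensitivity, specificity, Matthews correlation coefficient, ROC AUC),
    a synthetic proteome generator with a planted, hydrophobicity-governed
    cleavage rule for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
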