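Package: rotpssm
Title: Sequence-Based Protein-Protein Interaction Prediction with PSSM
    Descriptors and Rotation Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interactions from sequence alone.
    Proteins are represented as Position-Specific Scoring Matrices (PSSMs)
    produced by PSI-BLAST, reduced to fixed-length descriptors by
    two-dimensional principal component analysis (2DPCA) on a 20x20 Gram
    standardization of the profile, and protein pairs are classified by a
    Rotation Forest ensemble of decision trees. Includes PSSM and pair-list
    input/output, a thin PSI-BLAST wrapper, a stratified five-fold
    cross-validation protocol with accuracy, sensitivity, precision,
    Matthews correlation coefficient and ROC-AUC reporting, a cross-species
    train/test mode, and a seeded synthetic-data generator so the whole
    pipeline can be exercised without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rpart,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
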