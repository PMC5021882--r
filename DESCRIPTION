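Package: profoldr
Title: Protein Fold Classification from Multi-View Sequence and Structure Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts four complementary feature groups from proteins --
    eight-state secondary-structure descriptors parsed from DSSP files (40
    dimensions), amino-acid composition combined with
    composition/transition/distribution physicochemical descriptors (188
    dimensions), column averages of PSI-BLAST position-specific scoring
    matrices (20 dimensions), and binary functional-domain occupancy from
    RPS-BLAST hit tables -- and classifies SCOP-style folds with a
    multi-view ensemble that selects the best base classifier per feature
    group by stratified cross-validation and averages class posterior
    probabilities at prediction time. Includes parsers and writers for the
    external formats involved (FASTA, DSSP, ASCII PSSM, BLAST tabular, TSV
    feature matrices), a synthetic-data generator so the whole pipeline is
    testable without external databases, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    randomForest,
    e1071,
    nnet,
    MASS,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
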