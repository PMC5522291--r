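Package: rnam5c
Title: RNA 5-Methylcytosine Site Prediction from Pseudo Dinucleotide
    Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies 5-methylcytosine (m5C) modification sites in RNA
    sequences. Candidate cytosines are represented by fixed-width sequence
    windows, encoded as pseudo dinucleotide composition vectors built from
    auto- and cross-covariance of ten standardized physical-chemical
    dinucleotide properties, and classified with a random forest (100
    trees, 22-dimensional random subspace).  Includes benchmark-set
    construction from FASTA plus site annotations, jackknife and k-fold
    cross-validation with the sensitivity / specificity / accuracy /
    Matthews-correlation metric set, ROC/AUC, a seeded synthetic benchmark
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    Biostrings,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
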