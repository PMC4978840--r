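Package: gpcr188
Title: Sequence-Based GPCR Prediction with 188D Physicochemical Features and Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein sequences as G protein-coupled receptors (GPCRs)
    or non-GPCRs from primary sequence alone. Encodes each sequence as a
    188-dimensional vector (20 amino-acid composition values plus
    composition-transition-distribution encodings over eight three-class
    physicochemical partitions of the amino acids), builds stratified k-fold
    cross-validation splits, rebalances training folds with SMOTE, trains a
    Random-Forest classifier, and reports sensitivity, specificity, accuracy,
    Matthews correlation and ROC/AUC per fold with mean and standard-deviation
    aggregation. Includes FASTA and ARFF input/output, a greedy k-mer
    redundancy filter, and a seeded generator of synthetic receptor-like and
    background sequences so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    foreign,
    jsonlite,
    randomForest,
    seqinr,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
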