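Package: lpiforest
Title: Cascade Deep-Forest Prediction of lncRNA-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based prediction of long noncoding RNA (lncRNA) to
    RNA-binding protein interactions with a cascade deep forest. lncRNAs are
    featurized by k-mer nucleotide composition, proteins by a sliding-window
    segment-hash embedding compressed with a small autoencoder, and candidate
    pairs are scored by a layered ensemble of logistic regression, gradient
    boosting, random forest and extremely randomized trees whose
    class-probability vectors are concatenated with the original features at
    each layer. Includes cold-start cross-validation protocols that mask whole
    lncRNAs or proteins, balanced negative sampling from unknown pairs,
    AUC/AUPR evaluation with repeated runs, ranking of unknown pairs, and a
    seeded synthetic-data generator with planted motif-driven signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
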