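Package: cfscreen
Title: Correlation-Based Feature Selection and Consensus Virtual Screening
Version: 0.1.0
Authors@R: person("QSAR", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A ligand-based virtual-screening toolkit for binary activity
    classification from mixed descriptor/fingerprint feature tables.
    Provides activity binarization under multiple IC50 thresholds,
    two-stage feature filtering (zero-variance and Kendall tau-a
    redundancy), correlation-based feature subset selection (CFS merit)
    with best-first, genetic, geometric particle-swarm and subset-size
    forward-selection searches, decision-tree / random-forest /
    naive-Bayes classifiers with cross-validated hyperparameter tuning
    (ROC AUC, Matthews correlation), and chunked unanimous-consensus
    screening of large compound libraries with Tanimoto nearest-neighbor
    novelty annotation. Includes a synthetic-data generator with planted
    informative, redundant, constant and noise columns for end-to-end
    testing without proprietary descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
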