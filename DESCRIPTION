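Package: phosphoseed
Title: Fungal Phosphorylation Site Prediction with Offspring-Competition
    Genetic Algorithm Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein phosphorylation sites (S/T/Y) from sequence
    alone.  Candidate sites are represented as 41-residue fragments, encoded
    with physicochemical descriptor blocks (AAC, EAAC, CTDC, PAAC,
    quasi-sequence-order, positional one-hot) and with distributed k-mer
    embeddings trained by a subword-aware skip-gram model.  Features are
    reduced by importance-ranked sequential forward selection and then by an
    offspring-competition genetic algorithm to a fixed-size subset on which
    a radial-kernel support-vector machine is trained and evaluated
    (accuracy, sensitivity, specificity, Matthews correlation, AUC).  A
    synthetic-data generator with planted positional motifs makes every
    stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    methods,
    ranger,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
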