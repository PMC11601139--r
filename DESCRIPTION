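Package: adrminer
Title: Mining and Classifying Adverse Drug Reaction Posts in Social Media Text
Version: 0.1.0
Authors@R:
    person("ADRminer", "Developers", email = "adrminer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for detecting adverse-drug-reaction (ADR) posts in
    consumer social-media text: lexicon-based tagging of drug brand names and
    ADR terms, drug-to-ADR association-rule mining (support/confidence/lift)
    used to filter candidate posts, skip-gram word embeddings trained on the
    filtered corpus, a bidirectional LSTM binary classifier (with GRU and
    CNN-Bi-LSTM variants) implemented natively, and a full evaluation suite
    (confusion matrix, precision/recall/F1, ROC/AUC threshold sweeps, Cohen's
    and Fleiss' kappa). A synthetic-corpus generator emulates the statistical
    structure of labeled pharmacovigilance post collections so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
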