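Package: doaEEG
Title: Depth-of-Anaesthesia Estimation from Single-Channel EEG via Sample Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating a 0-100 depth-of-anaesthesia (DoA) index
    from frontal single-channel EEG. Includes noise-assisted multivariate
    empirical mode decomposition (N-A-MEMD) for artefact filtering with
    IMF2+IMF3 reconstruction, window-wise Sample Entropy (plus Permutation
    Entropy and recurrence quantification comparators), regression of the
    entropy feature onto a BIS-like reference index with Random Forest,
    support vector and neural-network models, and an evaluation battery
    (Pearson correlation, mean absolute error, ROC/AUC at the awake
    threshold, four-phase ANOVA on ranks with Student-Newman-Keuls pairwise
    tests). A synthetic anaesthesia-session generator with a known
    consciousness trajectory makes the whole pipeline testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    randomForest,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
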