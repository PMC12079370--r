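Package: classrsa
Title: Inter-Subject Representational Similarity Analysis for Classroom
    fNIRS Hyperscanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting knowledge representation and construction in
    multi-subject classroom fNIRS recordings: quality control and hemodynamic
    signal conditioning (artifact screening, steady-state trimming, global
    component removal by spatial PCA, zero-phase band-pass filtering,
    z-scoring), event-level inter-subject representational similarity analysis
    against topic-vector knowledge matrices with phase-randomization and
    shuffling permutation nulls and Benjamini-Hochberg correction,
    event-boundary contrasts, leave-one-dyad-out decoding of knowledge
    structure, inter-subject pattern correlation (pISC) for neural and recall
    data, and time-lagged teacher-student representational synchronization.
    Includes a synthetic cohort generator with known ground truth so that
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
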