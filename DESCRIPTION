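Package: hierloc
Title: Hierarchical Profile-Kernel SVM Prediction of Protein Subcellular Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein subcellular localization from sequence profiles
    with a hierarchy of binary support vector machines, one per internal node
    of a domain-of-life specific sorting tree (3 classes for archaea, 6 for
    bacteria, 18 for eukaryota). Similarity between proteins is measured by a
    profile k-mer string kernel computed efficiently by a pruned trie
    traversal; per-node decision values are calibrated with Platt scaling and
    combined along the root-to-leaf path into an integer reliability index
    (0-100). Includes the full evaluation harness (stratified cross-validation,
    per-class accuracy/coverage/geometric average, overall Qn, bootstrap
    standard errors, reliability-threshold curves, fragment-robustness
    benchmark), a redundancy-reduction utility based on length-dependent
    identity thresholds, and a synthetic sequence-profile generator with
    class-specific sorting-signal motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    kernlab,
    Biostrings,
    ape,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
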