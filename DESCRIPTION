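Package: fsbc
Title: Fast String-Based Clustering for HT-SELEX Sequence Pools
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate aptamer target-binding regions in a single
    round of HT-SELEX sequencing data by ranking variable-length
    over-represented strings with a composition-aware Z-score and greedily
    clustering sequences by the ranked strings.  The containment probability
    of a string in random i.i.d. text is computed by a border-corrected
    recurrence, candidate strings are found by a Z-score-pruned extension
    search between a minimum and maximum length, Z-scores are standardized
    within each length class for cross-length ranking, and clusters are
    extracted greedily in rank order.  Includes a synthetic SELEX-pool
    generator with planted motifs, an exact containment-probability oracle
    for validation, and ROC/AUC evaluation of cluster rankings against
    binding labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
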