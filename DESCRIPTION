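Package: somaticdriver
Title: Cancer-Type-Specific Annotation of Missense Driver Mutations
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates driver and passenger training examples from somatic
    mutation catalogs using recurrence and proximity-window rules, imputes
    missing values in precomputed per-mutation feature tables by k-nearest
    neighbours within gene, selects a feature set by a hybrid exhaustive plus
    hill-climbing search under repeated stratified cross-validated ROC AUC,
    scores mutations with a class-weighted support vector machine, and emits
    three-way calls (driver, no-call, passenger) with empirical
    percentile-based confidence scores. Includes evaluation utilities
    (ROC AUC and recall, score-prevalence correlation, hypergeometric
    enrichment of predicted drivers in gene panels, matched-model score
    comparisons) and a synthetic fixture generator for catalogs and feature
    tables with known class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
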