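Package: mirank
Title: Correlation-Grouped Ranking of miRNA Target-Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates paired two-class miRNA and mRNA expression profiles
    by grouping mRNAs under the miRNA whose expression they anti-correlate
    with, scoring each group by internally cross-validated classification,
    building cumulative top-j classifiers, and aggregating per-iteration
    rankings across Monte-Carlo cross-validation into significance-ranked
    miRNA and gene lists via beta order-statistic rank aggregation. Includes
    a synthetic paired-expression generator with planted regulator structure
    for end-to-end validation, class-imbalance under-sampling, and an
    external-cohort validation mode.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
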