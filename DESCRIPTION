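Package: blgpa
Title: Literature Knowledge-Graph Path Analysis for Drug-Gene Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-gene interaction links over literature-derived
    biomedical knowledge graphs. Implements bounded simple-path enumeration
    between drug and gene nodes, positional semantic-encoding features
    (per-position counts of UMLS semantic types and relations), support-ranked
    relational-chain (path-ranking) features, a random-forest link classifier
    with positive-negative sampling regimes and leakage-free cross-validation,
    and a pruned decision-tree surrogate that renders per-pair decision rules.
    Includes a synthetic knowledge-graph generator with planted relational
    chains for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
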