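Package: hypotrees
Title: Rank-Percentile Decision-Tree Ensembles for Hypoxia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference-free classification of individual transcriptomes as
    hypoxic or normoxic. Expression values are converted to within-sample
    rank percentiles, so samples can be classified one at a time without
    between-sample normalization. The package grows small CART decision
    trees on percentile data, selects informative genes with random-forest
    permutation importance (mean decrease in accuracy), mass-generates and
    accuracy-filters candidate trees, and classifies bulk samples or
    spatial-transcriptomics spots by consensus probability across a curated
    tree ensemble. A synthetic-cohort generator with known hypoxia-responsive
    genes makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
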