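Package: dsskit
Title: Quantitative Drug Sensitivity Scoring from Dose-Response Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative drug sensitivity scoring in high-throughput
    dose-response screens of cancer cell lines and primary patient cells.
    Fits four-parameter logistic dose-response models, computes the drug
    sensitivity score (DSS) as a closed-form integral of the fitted response
    above an activity threshold with three normalization variants, the
    discrete Activity Area comparator and relative IC50, and differential
    scores against control samples. Includes skewness-based detection of
    drug-sensitive responder sub-groups (D'Agostino test), ROC/AUROC and
    DeLong comparisons of response metrics, Ward/Spearman clustering of drug
    response profiles with external cluster-index evaluation and permutation
    tests, kinase-addiction (KISS) scoring against drug-target matrices with
    network export, and seeded synthetic-data generators for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
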