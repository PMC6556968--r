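Package: telomark
Title: Telomerase-Associated Multi-Omics Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Confounder-adjusted screening of multi-omics features between
    TERT-high and TERT-low tumors using propensity-score matching weights,
    weighted regression with permutation nulls, weighted gene co-expression
    network construction with module and hub discovery and preservation
    testing, miRNA target aggregation and cluster scoring, and unsupervised
    random-forest dissimilarity subtyping with survival comparison. Includes
    a synthetic multi-omics cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    cluster,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
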