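Package: fminer
Title: Mining Multi-Ingredient Herbal Prescription Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining collections of multi-ingredient herbal
    prescriptions (formulas): term standardization against a synonym lookup
    table, long/wide transaction encoding, frequency and traditional
    attribute statistics (natures, flavors, meridian tropism, efficacy
    classes), Apriori association-rule mining with batch parameter-grid
    exploration, phi-coefficient correlation matrices with chi-square
    p-values, co-occurrence networks, agglomerative clustering with
    multi-index voting for the number of clusters, and intra-/inter-group
    formula similarity analysis (Jaccard matrices, group similarity scores,
    role-weighted similarity, thresholded similarity networks with degree
    centrality). Includes a seeded synthetic prescription-data generator
    with Zipf-like ingredient frequencies and planted core combinations,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
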