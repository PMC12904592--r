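Package: dprule
Title: Testing the Development-to-Phenotype Rule with Single-Cell Atlases and Phenotype Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, for each gene, a developmental expression signature from a
    single-cell embryo atlas (fraction of cells active at each cell-type-by-stage
    coordinate) and a phenotypic signature from a non-negative matrix factorization of
    an ancestor-closed gene-by-phenotype ontology matrix. Tests whether developmental
    similarity predicts phenotypic similarity (the development-to-phenotype rule),
    classifies rule-breaking genes from Loess residuals, scores pleiotropy and its
    developmental localization with resampling nulls, and identifies cell types that
    mediate latent phenotype components through one-sided Kolmogorov-Smirnov tests on
    per-cell regression residuals. Includes a synthetic-data generator with planted
    ground truth so every stage of the analysis has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
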