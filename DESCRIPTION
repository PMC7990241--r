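Package: metabopipe
Title: Preprocessing, Statistics and Multi-Platform Fusion for Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless pipeline for sample-by-metabolite feature tables:
    spreadsheet ingestion with column-role assignment and validation,
    per-group MNAR/MCAR missingness classification with six imputation
    strategies (zero, half-minimum, mean, median, k-nearest-neighbour,
    iterative random forest), pretreatment (sample normalization,
    log/root transformation, autoscale/Pareto/range/vast/level scaling),
    per-metabolite Wilcoxon and ANOVA + Tukey HSD statistics with volcano
    selection, PCA, hierarchical clustering, thresholded correlation
    networks, and three multi-platform fusion methods (concatenation,
    PCA score fusion, multi-block PCA weighting), plus a seeded synthetic
    data generator with ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    readxl,
    jsonlite,
    stats,
    utils,
    tools,
    ggplot2,
    generics,
    ape,
    ranger,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
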