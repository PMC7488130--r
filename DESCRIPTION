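Package: modulomics
Title: Per-Patient Multi-Omics Gene Module Discovery and Drug Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates two or more omics layers (gene expression, copy
    number, methylation, mutation status) patient by patient to find gene
    modules: groups of genes that share common genomic features within one
    individual. Two clustering strategies are provided, an unsupervised
    random-forest proximity matrix clustered with k-means (with optional
    silhouette-based selection of the number of modules) and a logic-rule
    binarization clustered with k-modes. Each module is scored for its
    level of genomic alteration and for druggability against a user-supplied
    gene-drug association table, and the most activated (or suppressed)
    druggable module per patient is selected automatically. Includes a
    synthetic-cohort generator with planted module structure for validation,
    ggplot2 visualisations and a static HTML report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    mclust,
    purrr,
    randomForest,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
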