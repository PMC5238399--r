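Package: droughtdeg
Title: Drought-Responsive Gene Classification and Annotation Networks for
    Tag-Count RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for paired single-library RNA-seq comparisons
    between drought-resistant and drought-sensitive Brassica napus cultivars
    under osmotic stress and control conditions. Implements an exact
    Poisson-model test for differential expression between two tag-count
    libraries with RPKM normalisation and Benjamini-Hochberg FDR control,
    Venn-region classification of drought-responsive genes into
    resistant-specific, sensitive-specific and common categories with
    two-round fold-change threshold filters, hypergeometric GO/KEGG
    over-representation tests with Bonferroni correction, tripartite
    gene-process-pathway network construction with six weighted one-mode
    projections and their degree statistics, average-linkage clustering
    helpers, and a seeded synthetic-data generator with planted
    differential-expression and enrichment structure for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
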