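Package: pairomics
Title: Expression Exploration, Enrichment and Paired Multi-Omics Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for exploring normalized gene-by-sample expression
    matrices (transcriptome or proteome): variable-gene ranking, hierarchical
    clustering, empirical-Bayes moderated-t differential expression,
    over-representation analysis, gene set enrichment analysis (GSEA) with
    signal-to-noise phenotype ranking and permutation significance,
    single-sample GSEA, and an integration workflow for paired omics
    datasets built on reciprocal enrichment of derived differential
    signatures and overlap concordance statistics (Fisher's exact test,
    Cohen's kappa, Jaccard index). Includes a synthetic paired-omics
    generator with planted differential expression and tunable cross-omics
    concordance, and a command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    optparse
Config/testthat/edition: 3
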