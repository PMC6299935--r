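Package: exprkit
Title: Exploratory, Enrichment and Pathway Analysis for Gene Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for gene-level expression matrices: low-count
    filtering and started-log transformation with skew detection, library-size
    QC by ANOVA, gene-identifier conversion with automatic species detection,
    exploratory analysis (top-variance selection, hierarchical and k-means
    clustering, PCA), hypergeometric gene-set enrichment with
    Benjamini-Hochberg correction and redundancy summarisation of enriched
    terms, parametric gene-set Z-scores (PAGE) with per-sample pathway
    activity matrices ranked by ANOVA and spread, pathway analysis of PCA
    loadings, and promoter scanning with position weight matrices followed by
    best-score t-test motif enrichment. Includes seed-deterministic
    negative-binomial simulators for counts, gene sets, promoters and
    identifier-mapping tables, and a pipeline driver tying the stages
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
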