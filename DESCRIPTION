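Package: pubpulse
Title: Publication Dynamics of GWAS-Associated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how genome-wide association studies (GWAS) redirect
    biomedical research effort across human genes. Provides ingestion of
    gene-publication link tables, OMIM-style gene-disease maps and
    GWAS-catalog-style association tables; Gini/Lorenz inequality analysis of
    publications across genes; a matched-control publication-excess statistic
    with square-root variance stabilization and its regression model; a
    saturating Poisson publication-rate model with maximum-likelihood fitting
    and Bonferroni-corrected detection of exceptionally studied ("hot")
    gene-years; and a synthetic-data generator so the entire pipeline runs
    and is testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
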