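Package: drivescope
Title: X-Chromosome Regulation and Meiotic Drive in Testis Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterising X-chromosome regulation
    (meiotic sex chromosome inactivation, dosage compensation) and the
    transcriptomic consequences of X-linked meiotic drive in testis
    single-cell RNA-seq data. Provides quality-control filters for droplet
    count matrices, per-cell X:autosome expression metrics and an
    X-inactivation classifier, pseudobulk aggregation with TMM library
    normalisation and the log2(X:A) dosage statistic, a negative-binomial
    conditional exact test for pseudobulk differential expression between
    standard and drive genotypes, a binomial model of chromosomal enrichment
    of differentially expressed genes with a cell-resampling pseudo-replicate
    null, random-intercept binomial models of cell-type abundance,
    haploid/diploid classification from per-cell allele counts, DNA coverage
    tests as a copy-number proxy, and a calibrated synthetic-data generator
    with truth tables for every programmed effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    lme4,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
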