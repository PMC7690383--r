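Package: methresp
Title: DNA Methylation Classifiers of Neoadjuvant Chemoradiotherapy Response in Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for building and evaluating CpG methylation
    classifiers of pathological complete response (pCR) to neoadjuvant
    chemoradiotherapy in locally advanced rectal cancer. Provides
    differential-methylation testing on Illumina EPIC-style beta values with
    empirical-Bayes variance moderation, exclusive-set (Venn) partitioning of
    differentially methylated probes, genomic-context summaries, SD-filtered
    hierarchical clustering with Fisher-exact cluster enrichment, AUC-ranked
    feature selection with stepwise redundancy elimination, a diagonal linear
    discriminant (DLDA) classifier with leave-one-out cross-validation and
    cross-platform (microarray to bisulfite-pyrosequencing) threshold
    recalibration, and methylation-expression integration with regulatory
    interval overlap. A synthetic-cohort generator emulates the statistical
    structure of a three-group (normal tissue, complete and incomplete
    responder) methylation study so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
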