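Package: famscore
Title: Family-Based GWAS Prioritization and Sex-Specific Genetic Scores
    Under a Liability-Threshold Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a prioritization pipeline for genome-wide association
    studies of multiplex families: quality control (Hardy-Weinberg exact test,
    call rate, minor allele frequency, whole-family Mendelian-error masking),
    family-based transmission tests under additive, dominant and recessive
    genetic models with sex stratification, sibling case-control association
    with cluster-robust estimating equations, convergent functional-genomics
    scoring of SNP-gene pairs, and sex-specific genetic scores whose
    discrimination (AUC) is converted to the proportion of genetic variance
    explained on the liability scale using prevalence and sibling recurrence
    risk. Includes a synthetic multiplex-family simulator with a sex-specific
    liability-threshold architecture and family-level bootstrap machinery for
    empirical confidence intervals, selection-inflation checks and a
    genetic-model reproducibility index.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
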