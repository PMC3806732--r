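Package: microsig
Title: Group-Specific Microbial Community Signatures from OTU Tables and
    t-RFLP Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for discovering and evaluating
    group-specific signatures in cohort microbiome surveys. Implements
    t-RFLP peak-profile standardization (1% area floor and
    renormalization), the arcsine-square-root variance-stabilizing
    transform, Shannon diversity and equitability, Bray-Curtis
    dissimilarity with non-metric multidimensional scaling,
    prevalence-based core-microbiome and group-signature discovery with
    Venn partitioning, a consortium prediction-likelihood statistic,
    per-taxon ANOVA and t-tests on the transformed scale with optional
    false-discovery-rate control, and random-forest discrimination of
    group membership with per-class sensitivity and specificity. A
    synthetic-cohort generator with planted core taxa, group consortia
    and group-wise evenness effects provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
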