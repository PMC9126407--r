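Package: omicschain
Title: Multi-Omics cis-QTL, Co-Localization, Predicted-Expression and
    Mendelian-Randomization Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links genetic variants, tissue gene expression, blood protein
    levels and a binary disease outcome through a tested analysis chain:
    locus-wide additive cis-QTL scans with covariate adjustment and sex
    stratification, hierarchical (Simes + Benjamini-Bogomolov) false discovery
    rate control with priority LD pruning, Bayesian co-localization of trait
    pairs via Wakefield approximate Bayes factors, summary-statistics based
    association of genetically regulated expression with protein levels,
    two-sample Mendelian randomization with the ratio estimator and
    delta-method standard errors, and mediation analysis of expression ->
    protein -> disease causal chains. A synthetic-data generator with
    LD-structured genotypes and known causal architecture makes every stage
    testable without access-restricted cohort data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
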