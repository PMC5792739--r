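Package: crossconcord
Title: Cross-Species Concordance Screening for Metastasis-Associated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a cross-species comparative
    genomics workflow that nominates prognosis-associated genes whose
    expression change tracks metastatic capability in mouse melanoma cell
    lines. Provides gene-wise Cox proportional-hazards screening of patient
    cohorts with Benjamini-Hochberg control and dual-cohort direction
    intersection, negative-binomial Wald differential expression with
    median-of-ratios normalisation and FPKM summaries, orthologue
    resolution by protein identity, mouse-human direction concordance with
    a gene-sampling randomisation null, matched-normal-free somatic variant
    filtering, and 96-context mutational-signature extraction by
    non-negative matrix factorisation with cosine matching to reference
    signatures. A synthetic-data module generates every input with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
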