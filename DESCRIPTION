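Package: meqtlmap
Title: Multi-Cohort Methylation QTL Mapping, Meta-Analysis and Co-Localisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering methylation quantitative trait
    loci (meQTLs) across cohorts: genotype and probe quality control,
    rank-based inverse normal transformation and covariate residualisation of
    methylation beta-values, per-cohort cis/trans linear association scans
    with liberal candidate retention, DerSimonian-Laird random-effects
    meta-analysis, permutation-based false discovery rate thresholding with
    family-preserving shuffles, direction-consistency filtering, LD-based
    clumping with connectivity outlier calling, annotation enrichment with
    matched resampled backgrounds and TAD co-membership, classical-twin ACE
    variance decomposition, and summary-based Mendelian randomisation with
    the HEIDI heterogeneity test. Ships a synthetic multi-cohort data
    generator with known planted effects so every stage is testable without
    external data.
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
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
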