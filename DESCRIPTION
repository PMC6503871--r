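Package: epidrift
Title: Stochastic Epimutations, Epigenetic Clocks and Multi-Cohort
    Meta-Analysis of DNA Methylation Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-cohort analyses of epigenetic aging
    from DNA methylation beta matrices: calling stochastic epigenetic
    mutations (SEMs) by cross-sample interquartile-range fences, applying
    linear CpG clocks and deriving age-acceleration residuals (AA, EAA,
    IEAA), fitting per-cohort linear exposure models with categorical risk
    factors, pooling cohorts by restricted maximum likelihood (REML)
    random-effects meta-analysis with tau-squared and I-squared
    heterogeneity statistics, re-expressing SEM effects in years via a
    two-step Cohen's d standardization, and testing SEM loci for enrichment
    in genomic region sets by permutation. Includes a synthetic multi-cohort
    generator with recorded ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ggplot2,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
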