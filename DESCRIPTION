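Package: stressmwas
Title: Methylome-Wide Association Analysis of Early-Life Environments
    with Family-Structured Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for methylome-wide association studies (MWAS) of
    early-life environment and adult mental-health phenotypes in
    family-structured cohorts. Implements construction of eight
    early-life phenotypes (preterm birth, low birth weight, birth
    month, seasonal birth-date score, young parent, lone parent,
    urbanicity, population density) and a resilience-scale score;
    quality control and M-value computation for methylation arrays;
    two-stage mixed-model correction of the methylome for technical
    and familial/biological variation using plate, date and five
    pedigree-derived relationship matrices; two association engines (an
    empirical-Bayes moderated probewise linear model and a
    multi-component mixed-linear-model association that excludes the
    target probe and adjusts for blood cell composition); genomic
    inflation and QQ diagnostics; probe-number-bias-corrected gene-set
    enrichment; thresholded methylation profile scores with Nagelkerke
    and adjusted R-squared evaluation; kinship-aware phenotypic
    regression and CpG mediation analysis; and a synthetic cohort
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    fgsea,
    ranger
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
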