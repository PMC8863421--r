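# stressmwas

Methylome-wide association analysis of early-life environments and adult
mental health in family-structured cohorts, with a synthetic cohort
generator that gives every stage planted ground truth.

Epidemiological cohorts with DNA methylation arrays (Illumina 450K/EPIC),
pedigree information and linked early-life records pose a specific chain
of analysis problems: constructing exposure phenotypes from raw records,
cleaning and correcting CpG-by-sample M-value matrices for technical
batches and familial covariance, testing hundreds of thousands of CpGs
for association with each phenotype while controlling relatedness and
blood cell composition, and asking whether methylation carries signal
from early life into adult mental health (overlap of annotated genes,
methylation profile scores, mediation). `stressmwas` implements that
chain end to end for analysts working in R with Bioconductor containers.

## What is implemented

* **Phenotypes** — eight early-life environment constructors (preterm
  birth < 37 weeks; low birth weight below a sex x gestation centile
  table; April–October birth; the seasonal birth-date score
  `y = -cos(2*pi*(date+10)/365)`; young parent < 21; lone parent by
  birth-region residence; urbanicity; population density) plus a
  PC1-based resilience-scale score with random-forest imputation.
* **Preprocessing** — detection/beadcount/exclusion-list QC with the
  exact boundary conventions; M-value computation; per-CpG mixed-model
  correction for (1) plate and blood-draw date (crossed random
  intercepts + technical fixed effects) and (2) five familial covariance
  components G/K/F/C/S with sex, age and cell proportions, returning
  whitened residuals.
* **Two association engines** — MWAS 1: probewise OLS with
  empirical-Bayes moderated t-statistics (M-values dependent); MWAS 2: a
  multi-component mixed-linear-model association that groups lead probes
  from a marginal scan, fits them as random effects *excluding the
  target probe and its 50 kb neighbourhood*, and adjusts for
  haematological cell counts (phenotype dependent).
* **Post-association** — genomic inflation lambda, Bonferroni
  thresholds, QQ/Miami exports, location-based gene annotation, and
  gene-set enrichment corrected for probe-number bias via Wallenius'
  noncentral hypergeometric distribution.
* **Profile scores** — thresholded discovery-weight scores evaluated by
  Nagelkerke (binary) or adjusted (continuous) R² increments over
  covariates, with a seven-threshold sweep and a discovery/target
  leakage guard.
* **Kinship GLMM + mediation** — phenotypic regression with a
  kinship-structured random effect (REML / PQL) and product-of-
  coefficients mediation with percentile bootstrap intervals.
* **Synthetic cohorts** — nuclear-family pedigrees, variance-component
  methylomes with plate/date/cell structure, liability-threshold binary
  phenotypes at configured prevalences, seasonal cell-composition
  coupling, and a `SimTruth` record of every planted effect.

## Worked example

```r
library(stressmwas)

design <- cohortDesign(nIndividuals = 300, nCpgs = 500, nCausal = 3,
                       effectSize = 0.3, seed = 7)
coh <- simulateCohort(design)
coh$mset
#> MValueSet: 500 CpGs x 300 samples [stage: raw]

tech <- correctTechnical(coh$mset, fixed = as.data.frame(
  SummarizedExperiment::colData(coh$mset))[, c("plate_position", "set",
                                               "clinic", "year", "weekday")])

t1 <- runMwas1(tech, coh$samples$brs, n_pcs = 10)
t2 <- runMwas2(tech, coh$samples$brs, n_pcs = 10)

genomicInflation(t1$p)$lambda
#> [1] 1.046239
bonferroniThreshold(0.05, nrow(t1))
#> [1] 1e-04
head(t1[order(t1$p), c("cpg_id", "effect", "se", "p")], 3)
#>        cpg_id     effect         se            p
#> 469 cg0000469  0.2870727 0.05143960 2.580858e-08
#> 46  cg0000046 -0.2654467 0.05154480 2.754532e-07
#> 116 cg0000116  0.1674458 0.05178952 1.235752e-03
causalSites(coh$truth, "brs")
#>   phenotype    cpg_id slope
#> 7       brs cg0000046  -0.3
#> 8       brs cg0000469   0.3
#> 9       brs cg0000139   0.3
```

The two top hits are planted causal sites, recovered with effects and
signs near their true slopes of +/-0.3 (the third planted site,
cg0000139, is diluted by its liability construction in this draw);
`lambda` near 1 says the engine is calibrated on the remaining null
probes. `runMwas2` returns the same schema with `engine = "mwas2"`, and
`miamiExport(t1, t2)` produces the plot-ready signed `-log10` table.

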