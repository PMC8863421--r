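---
title: "Methods: methylome-wide association of early-life environments in family cohorts"
author: "stressmwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome-wide association of early-life environments in family cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmwas)
```

# Scope and model

`stressmwas` implements a complete methylome-wide association (MWAS)
analysis of early-life environment and adult mental-health phenotypes in a
family-structured cohort, together with a synthetic cohort generator that
makes every stage testable without access to restricted cohort data. The
pipeline runs, in order: phenotype construction, quality control and
M-value computation, a two-stage mixed-model correction of the methylome,
two association engines, inflation diagnostics and gene-set enrichment,
methylation profile scores, and kinship-aware phenotypic regression with
CpG mediation analysis.

Throughout, methylation is analysed on the M-value scale,
$M = \log_2(\mathrm{meth}/\mathrm{unmeth})$, which is approximately
variance-stabilized relative to the beta (fraction-methylated) scale.

## Phenotype constructors

Eight early-life environments are built from raw records with exposure
coded 1 and strict inequalities at every boundary (equality = unexposed):
preterm birth (gestation < 37 weeks), low birth weight (below a supplied
sex- and gestation-adjusted centile threshold table), birth month
(April-October inclusive), the continuous seasonal birth-date score
$y = -\cos\!\big(2\pi\,(\mathrm{date}+10)/365\big)$ (−1 at the winter
solstice, day 355; +1 at the summer solstice, day 172; 29 February mapped
to day 59.5), young parent (any parent under 21; the co-resident parent's
age for lone-parent records), lone parent (exactly one parent in the
child's region; neither parent present is missing, never 0), urbanicity
(membership of a configurable four-city set) and population density (a
(region, year) table lookup). Missingness propagates as `NA`; it is never
silently coerced to unexposed.

The resilience scale is scored as the first unrotated principal component
of six 1-5 Likert items: individuals answering fewer than five items are
dropped, remaining missing cells are imputed by iterative random-forest
regression (500 trees per forest, each incomplete item cycled against the
other five until the imputed values stabilise), and the component is
oriented so higher scores mean higher mean item response. Raw PC scores
are returned by default — the observed scale has an SD of several units —
with standardization available as an option; we do not assume an
undocumented rescaling. Whether items should be reverse-keyed before
scoring is exposed as an argument (`reverse_items`) rather than decided
internally, since item orientation is a property of the instrument
coding, not of the method.

Continuous phenotypes are centred and scaled to mean 0, SD 1 (sample-SD
convention) before association analysis, so effects are per SD.

## Quality control and correction

Sample QC removes samples whose fraction of probes with detection
$P > 0.05$ is $\ge 1\%$ (inclusive), predicted/recorded sex mismatches,
and a supplied list of multidimensional-scaling outliers (no
distance/cut-off rule is imposed here; detection is delegated). Probe QC
removes probes with beadcount $< 3$ in strictly more than 5% of samples,
probes where $\ge 0.5\%$ of samples fail detection, and probes on a
supplied cross-reactive/polymorphic exclusion list. The rules are
independent, so their application order cannot change the retained set.

Correction proceeds in two stages, each fitting one model per CpG with the
M-values as the dependent variable:

1. **Technical**: a linear mixed model with plate and blood-draw date as
   crossed random intercepts and plate position, measurement set, clinic,
   appointment year, weekday and any supplied control-probe principal
   components as fixed effects. Variance ratios are profiled out by REML
   through the Woodbury identity (the design cross-products are shared by
   all CpGs, so each CpG costs one small optimisation), and residuals come
   from Henderson's mixed-model equations — they are exactly orthogonal to
   every fixed-design column, and the intercept leaves them centred.

2. **Familial/biological**: a variance-component model with five
   relationship matrices — G (common genetic), K (kinship), F (nuclear
   family), C (couple), S (sibling) — as random-effect covariance
   structures and sex, age and six estimated blood cell proportions
   (CD8T, CD4T, NK, B cell, monocyte, granulocyte) as fixed effects,
   fitted per CpG by average-information REML (Haseman-Elston
   initialization, tolerance $10^{-6}$, at most 50 iterations; components
   hitting the zero boundary leave the AI system so the remaining
   components still update). The corrected value is the *whitened*
   residual $\hat\sigma_e V^{-1/2}(y - X\hat\beta)$. We whiten rather
   than subtract BLUPs because BLUP residuals have covariance
   proportional to $V^{-1}$, which anti-correlates relatives by
   construction; whitening leaves relatives uncorrelated under the
   fitted model and collapses to OLS residuals when every matrix is the
   identity. Components supplied as identical matrices are collapsed
   before fitting (their shares are not separately identifiable — the
   default simulation sets G = K), and a component equal to the identity
   is dropped, since its share is residual variance by definition.
   Non-convergent CpGs fall back to fixed-effects-only residuals and are
   flagged. Residuals are not re-centred per measurement set.

## Association engine 1: moderated probewise regression

Engine 1 fits one OLS model per CpG with the corrected M-values as the
dependent variable and the phenotype as the independent variable,
adjusting for measurement set, smoking status, pack years and the first
20 principal components of the corrected methylome (PC signs fixed by
making the largest-magnitude loading positive; the PCs default to the
corrected matrix, with the raw matrix available via an argument).
Residual variances are then shrunk by empirical Bayes: the scaled-F prior
$(d_0, s_0^2)$ is estimated by matching the first two moments of the log
residual variances (the trigamma inversion is a monotone bisection,
tolerance $10^{-8}$), the posterior variance is
$(d_0 s_0^2 + d\,s^2)/(d_0 + d)$, and the moderated $t$ is referred to a
$t$ distribution on $d + d_0$ degrees of freedom. With $d_0 = 0$ this is
exactly the OLS $t$-test; with equally dispersed variances $d_0 = \infty$
and every posterior equals $s_0^2$. The hyperparameter estimates agree
with the reference empirical-Bayes implementation (limma's `fitFDist`) to
numerical precision, which the test suite uses as an independent
cross-check — the package's own estimator is always the one used.

## Association engine 2: multi-component mixed model excluding the target

Engine 2 reverses the roles: the phenotype is the dependent variable.
A marginal scan (per-probe OLS of phenotype on probe plus the same
covariates as engine 1) ranks probes; probes are then stratified into
$m = 2$ groups, "lead" sites versus the rest. The default split is the
Bonferroni-corrected scan threshold $0.05/p$: with a lenient split such
as $P < 0.05$, five percent of probes — selected *because* they correlate
with the phenotype — are fitted as a random effect, which absorbs the
phenotype's chance alignment with the methylome and visibly deflates the
test statistics at desk scale (we observed $\lambda \approx 0.4$–$0.8$ on
null cohorts of 500 samples x 2000 probes). With the Bonferroni split a
null phenotype yields an empty lead group, the model collapses to a
single whole-methylome relationship matrix, and both the genomic
inflation factor and the empirical type-I error are calibrated. The cut
points remain configurable.

Each group $g$ contributes a methylome relationship matrix
$A_g = Z_g' Z_g / p_g$ over row-standardized probes, excluding the target
probe and all probes within 50 kb of it (configurable), so the target's
own signal never sits in the covariance it is tested against. The test is
a REML fit of the variance components followed by a generalized least
squares Wald test of the target probe's fixed effect, with five blood
cell counts (basophil, eosinophil, lymphocyte, monocyte, neutrophil)
as additional fixed effects. Binary phenotypes are analysed as 0/1 in the
linear mixed model, matching the procedure the engine reproduces.

Re-estimating the variance components for every target ("exact" mode) is
$O(n^3)$ per probe and unusable methylome-wide, so the default "approx"
mode estimates them once from the target-free model, freezes them, and
applies each target's exclusion as a low-rank Woodbury downdate of the
covariance (with divisors kept at the full group sizes — an $O(k/p)$
approximation). The mode is recorded on the output; the two modes agree
to about $10^{-3}$ on effects in the test suite, and exactly when the
exclusion set is empty.

## Diagnostics, annotation and enrichment

The genomic inflation factor is
$\lambda = \mathrm{median}\,\chi^2_{\mathrm{obs}} / \mathrm{median}\,\chi^2_1$
(null median $\approx 0.4549$), computed from $\chi^2$ quantiles of the
P-values. QQ exports pair each order statistic with its uniform
expectation $(i - 0.5)/n$ and a pointwise 95% beta band. Miami exports
place engine 1 on the $\log_{10}$ scale (downwards) and engine 2 on
$-\log_{10}$ (upwards), keep the full probe union (missing cells stay
`NA`), and draw the significance line at the Bonferroni threshold
$\alpha/n_{\mathrm{tests}}$ (0.05/713522 $= 7.01\times10^{-8}$ at the
full methylome; 0.05/8 $= 6.25\times10^{-3}$ across the eight
environments).

Gene-set over-representation corrects for probe-number bias: genes
carrying more probes are more likely to contain a significant CpG by
chance, so each set is tested with Wallenius' noncentral hypergeometric
distribution, the odds weight being the ratio of mean probes-per-gene
inside versus outside the set (computed by the exact integral
representation of the Wallenius density, normalized over the support;
odds 1 dispatches to the central hypergeometric exactly). Unadjusted and
Benjamini-Hochberg P-values are both reported; the unadjusted column
reproduces the decision scale the pipeline's enrichment conclusions are
stated on, with the stricter FDR column alongside.

## Methylation profile scores

Discovery-set summary statistics are thresholded at
$P < 10^{-7}, \dots, 10^{-1}$; each target-set sample's score is the sum
of discovery effect sizes times its M-values over the selected CpGs.
Binary outcomes are evaluated by the Nagelkerke $R^2$ *increment* of the
score over a sex + age + PC covariate model,
$(1 - e^{(2/n)(\ell_0-\ell_1)})/(1 - e^{(2/n)\ell_0})$ with the
covariate-only likelihood as $\ell_0$, with a likelihood-ratio P;
continuous outcomes by the adjusted-$R^2$ increment with a partial-F P.
All seven thresholds are evaluated and reported with the best-$R^2$
threshold flagged; because that threshold is chosen after seeing the
$R^2$, its P-value is optimistic, which the selection-aware null test in
the suite quantifies (the best threshold beats the family gate
$0.05/8$ in well under 5% of null sweeps). Any sample shared between
discovery and target sets is a hard error, and external weight files
(cpg_id, effect) score directly without a discovery stage.

## Phenotypic regression and mediation

Associations of adult mental health with each early-life environment are
fitted with a kinship-structured random effect: Gaussian outcomes by
exact one-ratio REML through the eigendecomposition of the kinship
matrix, binary outcomes by penalized quasi-likelihood on the logit scale
(the kinship variance re-estimated on the working response each
iteration). PQL is known to bias variance components downward at low
prevalence; fixed-effect estimates are the quantity of interest here and
the recovery tests target those. Significance is judged against the
family gate $0.05/8$.

Mediation uses the product of coefficients: path $a$ from the linear
mediator model, paths $b$ and $c'$ from the outcome model (logistic for
binary outcomes, so the indirect effect $a\,b$ is on the log-odds
linear-predictor scale), with percentile bootstrap confidence intervals
and two-sided bootstrap P-values under a fixed seed (2000 draws by
default). We chose the transparent product-of-coefficients estimator over
quasi-Bayesian simulation because every piece is checkable against
closed-form oracles; for Gaussian outcomes total = direct + indirect
holds exactly on the point estimates.

# The synthetic cohort generator

The generator exists so that every downstream stage has ground truth. It
emulates, in order:

* **Pedigree**: independent nuclear families (two founders plus 0-3
  offspring; couples/trios/sibships mixed 0.3/0.4/0.3 by default),
  yielding all five relationship matrices (K from expected relatedness —
  full sibs and parent-offspring 0.5, spouses 0 — F/C/S as membership
  blocks, G = K unless configured apart). Whole families are assigned to
  one of two measurement sets, so the sets share no relatives.
* **Methylome**: per CpG, a bimodal baseline level plus familial
  component draws with configured variance fractions (defaults
  K = 0.15, F = 0.05, C = 0.02, S = 0.03 — the shares of
  methylation variance attributable to these components are not pinned
  down by published desk-scale references, so these are round, plausible
  placeholders, stated once and not tuned), plate (0.10) and blood-draw
  date (0.05) random intercepts, an optional cell-composition component,
  and independent residual noise. CpGs receive coordinates across 22
  autosomes.
* **Cell composition**: six whole-blood proportions around reference
  means with 15% relative between-individual noise. A seasonal amplitude
  parameter shifts the lymphoid/granulocyte balance by a cosine of birth
  day (summer-born higher lymphocyte share); the analyst-facing columns
  are *estimated* proportions (true + estimation error, not summing
  exactly to 1, as reference-based deconvolution behaves) plus precise
  haematological counts derived from the true composition.
* **Phenotypes**: binary traits by a liability-threshold model —
  liability = planted causal-CpG effects + a kinship-structured familial
  term (share 0.2) + residual scaled so the liability is standard
  normal, thresholded at $\Phi^{-1}(1-\mathrm{prevalence})$ (defaults
  3.5% for preterm birth, 13% for MDD, the rates the pipeline is
  designed around); a continuous trait built the same way and
  standardized; birth day uniform over the year with the derived
  seasonal score and April-October flag.

One global integer seed feeds a deterministic per-stage stream, so
regeneration is bitwise identical and stages can be re-run independently.

**What the generator does not emulate**: raw array intensities,
co-methylation/AR(1) correlation between neighbouring CpGs, non-Gaussian
M-value tails, cohort ascertainment, or genotype data. Passing tests on
this generator therefore demonstrate the correctness and calibration of
the *methods* under the stated covariance structure, not robustness to
every artefact of real arrays.

## The seasonal-confounding demonstration

When the seasonal amplitude is positive and the cell component feeds the
methylome, birth date, blood cell composition and the methylome are
mutually confounded — the structure behind the divergence between the two
engines on seasonal phenotypes. The demonstration conditions are fixed
once: amplitude 1.5 (a seasonal shift of 1.5 SD of between-individual
cell variation) and a cell variance fraction of 0.015, small because the
analysed matrix in the intended workflow has already been cell-corrected,
so only *residual* composition variance remains. On 500 samples x 2000
CpGs, the probewise engine run without cell-aware covariates inflates to
$\lambda > 5$ on the birth-date score, while the multi-component engine,
which fits haematological counts as fixed effects and the methylome
structure as random effects, stays calibrated
($\lambda \approx 1.0$-$1.1$).

One desk-scale caveat, documented rather than hidden: at 2000 probes the
confounded composition axis is a leading principal component of the
matrix itself, so either engine *with* 20 methylome PCs absorbs most of
the confounding ($\lambda \approx 1.1$). At two orders of magnitude more
probes the same axis hides below the noise eigenvalues and PC adjustment
no longer rescues the unadjusted engine — which is why the demonstration
isolates the cell-adjustment contrast by running both engines without PC
covariates.

# Numerical choices and problem sizes

* AI-REML: Haseman-Elston start, relative tolerance $10^{-6}$, max 50
  iterations, variance floor $10^{-8}\,\mathrm{var}(y)$, step-halving
  with boundary components removed from the AI system.
* Crossed-random-intercept REML: Nelder-Mead on log variance ratios,
  relative tolerance $10^{-10}$, with explicit boundary candidates so
  zero-variance fits are exact.
* Trigamma inversion: monotone bisection in log space, tolerance
  $10^{-8}$.
* Wallenius tails: adaptive quadrature at relative tolerance $10^{-12}$,
  density normalized over the support; odds 1 short-circuits to
  `phyper`.
* PC sign convention: largest-magnitude loading positive.
* Coordinates are 0-based half-open internally and BED on disk; 1-based
  input is accepted behind a flag.
* The test and validation suites run at deliberately small sizes chosen
  to keep the whole suite interactive on a single core: null-calibration
  cohorts of 500 samples x 2000 CpGs, variance-component recovery at 500
  samples x 30 CpGs, 100-replicate recovery loops at 400-500 samples,
  and 300-400-replicate calibration loops for enrichment and mediation.

# Known limitations

* The multi-component engine's default approximation freezes variance
  components across targets; per-target re-estimation is available but
  quadratic-to-cubic in cohort size per probe.
* PQL for binary kinship models attenuates variance components at low
  prevalence; a full Laplace fit over a dense kinship is out of scope.
* The five familial covariance structures share unit diagonals and
  partially overlapping blocks, so their individual shares are weakly
  identified at desk-scale cohort sizes; sums of collinear components
  (e.g. G + K) are the meaningful recovered quantities, and the
  correction stage collapses exact duplicates.
* Wallenius enrichment uses one odds weight per set (mean probe count in
  versus out), the same first-order bias correction used in practice,
  not a per-gene weighted multivariate distribution.
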