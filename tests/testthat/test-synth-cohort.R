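test_that("pedigree relationship matrices encode expected relatedness", {
  # couples only: spouses are unrelated, so K is the identity
  d <- cohortDesign(nIndividuals = 40, nCpgs = 10, seed = 3,
                    familyMix = c(couples = 1, trios = 0, sibships = 0))
  rel <- simulatePedigree(d)
  expect_equal(relMatrices(rel, "K")[[1]], diag(40), ignore_attr = TRUE)
  # but couples share the couple and nuclear-family environments
  expect_gt(sum(relMatrices(rel, "C")[[1]]) - 40, 0)

  # sibships: full sibs 0.5 in K, 1 in S; parent-child 0.5 in K
  d2 <- cohortDesign(nIndividuals = 50, nCpgs = 10, seed = 4,
                     familyMix = c(couples = 0, trios = 0, sibships = 1))
  rel2 <- simulatePedigree(d2)
  b <- batchInfo(rel2)
  K <- relMatrices(rel2, "K")[[1]]
  S <- relMatrices(rel2, "S")[[1]]
  sp <- sibPairs(rel2)
  expect_gt(nrow(sp), 2)
  expect_true(all(K[sp] == 0.5))
  expect_true(all(S[sp] == 0.5 * 0 + 1))
  f1 <- which(b$family_id == b$family_id[1])
  par <- f1[b$role[f1] == "founder1"]
  kid <- f1[b$role[f1] == "child"][1]
  expect_equal(K[par, kid], 0.5)

  # construction guarantees: all five matrices symmetric PSD, unit diagonal
  expect_true(validObject(rel2))
})

test_that("pedigree rejects designs the cohort cannot hold", {
  expect_error(cohortDesign(nIndividuals = 1, nCpgs = 5), "nIndividuals")
})

test_that("methylome regeneration is bitwise-identical under one seed", {
  d <- smallDesign(n = 60, p = 40, seed = 21)
  rel <- simulatePedigree(d)
  m1 <- simulateMethylome(d, rel)
  m2 <- simulateMethylome(d, rel)
  expect_identical(mValues(m1$mset), mValues(m2$mset))
  expect_identical(causalSites(m1$truth), causalSites(m2$truth))
  s1 <- simulatePhenotypes(d, m1$mset, m1$truth, rel)
  s2 <- simulatePhenotypes(d, m2$mset, m2$truth, rel)
  expect_identical(s1, s2)
})

test_that("variance fractions over 1 are an invalid design", {
  expect_error(
    cohortDesign(varFractions = c(G = 0.5, K = 0.5, F = 0.3, C = 0, S = 0,
                                  plate = 0, date = 0, cell = 0)),
    "sum")
})

test_that("pure-noise design yields uncorrelated samples", {
  d <- smallDesign(n = 80, p = 400, seed = 31, varFractions = noiseFractions)
  coh <- simulateCohort(d)
  M <- mValues(coh$mset)
  Mc <- M - rowMeans(M)
  C <- cor(Mc)
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.2)       # individual pair noise ~ 1/sqrt(400)
  expect_lt(abs(mean(off)), 0.02)
})

test_that("plate variance fraction is recovered in the generated matrix", {
  vf <- c(G = 0, K = 0, F = 0, C = 0, S = 0, plate = 0.5, date = 0, cell = 0)
  d <- cohortDesign(nIndividuals = 120, nCpgs = 5000, nCausal = 0, seed = 7,
                    varFractions = vf)
  coh <- simulateCohort(d)
  M <- mValues(coh$mset)
  plate <- batchInfo(coh$rel)$plate
  # method-of-moments plate variance component, averaged over CpGs
  k <- length(unique(plate)); n <- length(plate)
  m0 <- (n - sum(table(plate)^2) / n) / (k - 1)
  comp <- apply(M, 1, function(y) {
    a <- anova(lm(y ~ factor(plate)))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    sp <- max((msb - msw) / m0, 0)
    c(sp, msw)
  })
  share <- mean(comp[1, ]) / (mean(comp[1, ]) + mean(comp[2, ]))
  expect_gt(share, 0.42)
  expect_lt(share, 0.58)
})

test_that("familial covariance converges to the configured sigma^2 K", {
  vf <- c(G = 0, K = 0.4, F = 0, C = 0, S = 0, plate = 0, date = 0, cell = 0)
  d <- cohortDesign(nIndividuals = 90, nCpgs = 5000, nCausal = 0, seed = 13,
                    varFractions = vf)
  coh <- simulateCohort(d)
  M <- mValues(coh$mset)
  Mc <- M - rowMeans(M)
  S <- crossprod(Mc) / (nrow(M) - 1)
  target <- 0.4 * relMatrices(coh$rel, "K")[[1]] + 0.6 * diag(90)
  expect_lt(max(abs(S - target)), 0.1)
})

test_that("liability threshold controls binary prevalence", {
  d <- cohortDesign(nIndividuals = 2000, nCpgs = 20, nCausal = 0, seed = 17,
                    prevalences = c(preterm = 0.035, mdd = 0.13))
  coh <- simulateCohort(d)
  ci <- binom.test(sum(coh$samples$preterm), 2000, 0.035)$conf.int
  expect_true(0.035 >= ci[1] && 0.035 <= ci[2])
  ci2 <- binom.test(sum(coh$samples$mdd), 2000, 0.13)$conf.int
  expect_true(0.13 >= ci2[1] && 0.13 <= ci2[2])
  expect_error(
    simulatePhenotypes(cohortDesign(prevalences = c(preterm = 1.2)),
                       coh$mset, coh$truth, coh$rel),
    "prevalence")
})

test_that("planted slopes are recoverable and zero slopes give a null", {
  # zero effects: phenotype independent of every CpG
  d0 <- cohortDesign(nIndividuals = 600, nCpgs = 60, nCausal = 3,
                     effectSize = 0, seed = 23,
                     varFractions = noiseFractions, liabilityFamilial = 0)
  coh0 <- simulateCohort(d0)
  cs <- causalSites(coh0$truth, "brs")
  r <- cor(coh0$samples$brs, t(mValues(coh0$mset)[cs$cpg_id, ]))
  expect_lt(max(abs(r)), 2.58 / sqrt(600) * 1.5)

  # planted slope recovered by an independent OLS fit within 2 SE
  d1 <- cohortDesign(nIndividuals = 1000, nCpgs = 60, nCausal = 1,
                     effectSize = 0.3, seed = 29,
                     varFractions = noiseFractions, liabilityFamilial = 0)
  coh1 <- simulateCohort(d1)
  cs1 <- causalSites(coh1$truth, "brs")
  fit <- summary(lm(coh1$samples$brs ~ mValues(coh1$mset)[cs1$cpg_id, ]))
  est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
  expect_lt(abs(est - cs1$slope), 2 * se)
})

test_that("causal sites always exist in the simulated matrix", {
  d <- smallDesign(n = 50, p = 30, seed = 37)
  coh <- simulateCohort(d)
  expect_true(all(causalSites(coh$truth)$cpg_id %in%
                    rownames(mValues(coh$mset))))
})
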