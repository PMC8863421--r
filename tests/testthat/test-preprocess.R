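test_that("M-value computation matches its closed forms", {
  expect_equal(computeMValues(matrix(3), matrix(3)), matrix(0))
  expect_equal(computeMValues(matrix(8), matrix(2)), matrix(2))
  # beta 0.8 via intensities (0.8, 0.2): log2(0.8/0.2) = 2
  expect_equal(computeMValues(matrix(0.8), matrix(0.2)), matrix(2))
  expect_equal(betaToM(0.8), 2)
  expect_error(computeMValues(matrix(1), matrix(0)), "offset")
  expect_equal(computeMValues(matrix(1), matrix(0), offset = 1),
               matrix(1))       # log2((1+1)/(0+1))
  expect_error(computeMValues(matrix(-1), matrix(1)), ">= 0")
  expect_error(computeMValues(matrix(1:4, 2), matrix(1:2, 1)), "dimensions")
})

test_that("sample QC applies inclusive detection and sex-mismatch rules", {
  p <- 1000; n <- 5
  M <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("cg%04d", 1:p), paste0("S", 1:n)))
  pos <- data.frame(cpg_id = rownames(M), chrom = "chr1",
                    start = seq_len(p) * 100L, end = seq_len(p) * 100L + 1L)
  mset <- MValueSet(M, pos)
  det <- matrix(0.001, p, n)
  det[1:10, 1] <- 0.5     # exactly 1.0% failing -> removed (inclusive)
  det[1:9, 2] <- 0.5      # 0.9% failing -> retained
  out <- filterSamples(mset, det,
                       predicted_sex = c("F", "F", "F", "F", "F"),
                       recorded_sex = c("F", "F", "M", "F", "F"))
  expect_setequal(out$report$samples_removed$detection, "S1")
  expect_setequal(out$report$samples_removed$sex_mismatch, "S3")
  expect_equal(out$report$n_retained, 3)
  expect_equal(ncol(mValues(out$mset)), 3)
  expect_error(filterSamples(mset, det[1:10, ]), "aligned")
})

test_that("probe QC uses strict beadcount and inclusive detection bounds", {
  p <- 10; n <- 200
  M <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("cg%02d", 1:p), paste0("S", 1:n)))
  pos <- data.frame(cpg_id = rownames(M), chrom = "chr1",
                    start = seq_len(p) * 10L, end = seq_len(p) * 10L + 1L)
  mset <- MValueSet(M, pos)
  bead <- matrix(10, p, n, dimnames = dimnames(M))
  bead[1, 1:11] <- 1       # 5.5% below minimum -> removed
  bead[2, 1:10] <- 1       # exactly 5.0% -> retained (strict >)
  det <- matrix(0.001, p, n, dimnames = dimnames(M))
  det[3, 1] <- 0.5         # 0.5% failing -> removed (inclusive >=)
  thr <- qcThresholds(exclude_probes = "cg05")
  out <- filterProbes(mset, bead, det, thr)
  expect_setequal(out$report$probes_removed$beadcount, "cg01")
  expect_setequal(out$report$probes_removed$detection, "cg03")
  expect_setequal(out$report$probes_removed$exclusion_list, "cg05")
  expect_equal(out$report$n_retained, 7)

  # independent rules are order-insensitive
  s1 <- filterProbes(mset, bead, NULL, thr)$mset
  a <- filterProbes(s1, NULL, det[rownames(mValues(s1)), ], thr)
  s2 <- filterProbes(mset, NULL, det, thr)$mset
  b <- filterProbes(s2, bead[rownames(mValues(s2)), ], NULL, thr)
  expect_setequal(rownames(mValues(a$mset)), rownames(mValues(b$mset)))

  # clean input is a no-op
  clean <- filterProbes(mset, matrix(10, p, n), matrix(0.001, p, n),
                        qcThresholds())
  expect_equal(clean$report$n_removed, 0)
})

test_that("technical correction collapses to OLS without batch variance and
           stays orthogonal to the fixed design", {
  vf <- c(G = 0, K = 0, F = 0, C = 0, S = 0, plate = 0, date = 0, cell = 0)
  d <- cohortDesign(nIndividuals = 150, nCpgs = 40, nCausal = 0, seed = 41,
                    varFractions = vf)
  coh <- simulateCohort(d)
  fixed <- techCovariates(coh$mset)
  tech <- correctTechnical(coh$mset, fixed)
  X <- stressmwas:::buildDesign(fixed)
  R <- mValues(tech)
  # orthogonality to every fixed column (Henderson residual property)
  expect_lt(max(abs(R %*% X)), 1e-6)
  # no plate/date variance simulated: CpGs whose REML lands on the zero
  # boundary have exactly the OLS residuals; the rest differ only by the
  # shrinkage of chance between-group variance
  OLS <- t(qr.resid(qr(X), t(mValues(coh$mset))))
  rd <- as.data.frame(SummarizedExperiment::rowData(tech))
  zero <- rd$plate < 1e-10 & rd$date < 1e-10
  expect_gt(mean(zero), 0.2)
  expect_lt(max(abs(R[zero, ] - OLS[zero, ])), 1e-8)
  expect_gt(min(diag(cor(t(R), t(OLS)))), 0.95)
  # per-CpG mean ~ 0, dimensions unchanged
  expect_lt(max(abs(rowMeans(R))), 1e-6)
  expect_identical(dim(R), dim(mValues(coh$mset)))
  expect_identical(correctionStage(tech), "technical")
})

test_that("technical correction strips a planted plate share", {
  vf <- c(G = 0, K = 0, F = 0, C = 0, S = 0, plate = 0.4, date = 0.05,
          cell = 0)
  d <- cohortDesign(nIndividuals = 200, nCpgs = 60, nCausal = 0, seed = 43,
                    varFractions = vf)
  coh <- simulateCohort(d)
  tech <- correctTechnical(coh$mset, techCovariates(coh$mset))
  plate <- batchInfo(coh$rel)$plate
  plateShare <- function(M) mean(apply(M, 1, function(y) {
    a <- anova(lm(y ~ factor(plate)))
    a$`Sum Sq`[1] / sum(a$`Sum Sq`)
  }))
  share <- plateShare(mValues(tech))
  raw_share <- plateShare(mValues(coh$mset))
  # correction leaves at most the chance between-group share (~ (k-1)/(n-1))
  expect_lt(share, 0.05)
  expect_gt(raw_share, 0.15)     # few plates, so the realized share is noisy
  expect_gt(raw_share, 5 * share)
})

test_that("collinear fixed designs are rejected with the offending column", {
  d <- smallDesign(n = 60, p = 10, seed = 47)
  coh <- simulateCohort(d)
  fixed <- techCovariates(coh$mset)
  fixed$dup <- fixed$plate_position
  expect_error(correctTechnical(coh$mset, fixed), "dup")
})

test_that("biological correction with identity matrices returns OLS residuals", {
  d <- cohortDesign(nIndividuals = 80, nCpgs = 12, nCausal = 0, seed = 53,
                    varFractions = noiseFractions)
  coh <- simulateCohort(d)
  I80 <- diag(80)
  dimnames(I80) <- list(coh$samples$sample_id, coh$samples$sample_id)
  relI <- new("RelationshipMatrixSet",
              matrices = list(G = I80, K = I80, F = I80, C = I80, S = I80),
              batch = batchInfo(coh$rel))
  bio <- correctBiological(coh$mset, relI)
  cd <- as.data.frame(SummarizedExperiment::colData(coh$mset))
  X <- stressmwas:::buildDesign(
    data.frame(sex = cd$sex, age = cd$age,
               cd[, c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")]))
  OLS <- t(qr.resid(qr(X), t(mValues(coh$mset))))
  expect_equal(mValues(bio), OLS, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("biological correction decorrelates sibling pairs", {
  vf <- c(G = 0, K = 0.3, F = 0.1, C = 0, S = 0, plate = 0, date = 0,
          cell = 0)
  d <- cohortDesign(nIndividuals = 300, nCpgs = 80, nCausal = 0, seed = 59,
                    varFractions = vf,
                    familyMix = c(couples = 0.2, trios = 0.3, sibships = 0.5))
  coh <- simulateCohort(d)
  bio <- correctBiological(coh$mset, coh$rel)
  sp <- sibPairs(coh$rel)
  expect_gt(nrow(sp), 30)
  ctr <- function(X) X - rowMeans(X)
  pairCor <- function(X) mean(vapply(seq_len(nrow(sp)), function(i)
    cor(X[, sp[i, 1]], X[, sp[i, 2]]), 1.0))
  raw <- pairCor(ctr(mValues(coh$mset)))
  corrected <- pairCor(ctr(mValues(bio)))
  expect_gt(raw, 0.15)                  # siblings share K/2 + F = 0.25
  expect_lt(abs(corrected), 0.08)
  expect_true(all(SummarizedExperiment::rowData(bio)$reml_converged))
  expect_identical(correctionStage(bio), "biological")
})

test_that("non-PSD relationship matrices are rejected", {
  d <- smallDesign(n = 40, p = 8, seed = 61)
  coh <- simulateCohort(d)
  bad <- relMatrices(coh$rel)
  m <- bad$K; m[1, 2] <- m[2, 1] <- 5
  relBad <- coh$rel
  relBad@matrices$K <- m
  expect_error(correctBiological(coh$mset, relBad), "positive semidefinite")
})
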