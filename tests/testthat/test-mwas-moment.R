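test_that("marginal scan equals probewise OLS t under exchanged roles", {
  set.seed(81)
  n <- 120; p <- 40
  M <- matrix(rnorm(n * p), p, n,
              dimnames = list(paste0("cg", 1:p), paste0("S", 1:n)))
  M <- stressmwas:::standardizeProbes(M)   # standardize both variables
  ph <- as.numeric(scale(rnorm(n)))
  sc <- initialScan(M, ph)
  fp <- fitProbewise(M, ph)
  expect_lt(max(abs(sc$stat - fp$effect / fp$se)), 1e-8)

  # null scan statistics follow a central t distribution
  set.seed(82)
  M2 <- matrix(rnorm(150 * 2000), 2000, 150,
               dimnames = list(sprintf("cg%04d", 1:2000), paste0("S", 1:150)))
  sc2 <- initialScan(M2, rnorm(150))
  ks <- ks.test(sc2$stat, function(q) pt(q, df = 150 - 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("probe grouping honours cuts, merges empties, and finds signal", {
  scan <- data.frame(cpg_id = paste0("cg", 1:1000),
                     p = seq(0.0005, 0.9995, length.out = 1000))
  g <- groupProbes(scan, m = 2, p_cuts = 0.05)
  expect_equal(mean(g == 1), 0.05, tolerance = 0.01)
  expect_identical(unique(groupProbes(scan, m = 1)), 1L)
  expect_warning(g2 <- groupProbes(scan, m = 2, p_cuts = 1e-9), "merged")
  expect_identical(unique(g2), 1L)

  # planted probes land in the lead group across replicates
  set.seed(83)
  hits <- vapply(1:20, function(r) {
    n <- 400
    M <- matrix(rnorm(80 * n), 80, n,
                dimnames = list(paste0("cg", 1:80), paste0("S", 1:n)))
    ph <- 0.5 * M[11, ] + rnorm(n)
    sc <- initialScan(M, ph)
    g <- suppressWarnings(groupProbes(sc, m = 2, p_cuts = 0.05 / 80))
    g[["cg11"]] == 1 && which.max(abs(sc$stat)) == 11
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("component matrices match a brute-force oracle and PSD/trace laws", {
  set.seed(84)
  n <- 30; p <- 50
  M <- matrix(rnorm(n * p), p, n,
              dimnames = list(paste0("cg", 1:p), paste0("S", 1:n)))
  pos <- data.frame(cpg_id = rownames(M), chrom = "chr1",
                    start = seq_len(p) * 1000L)
  grouping <- setNames(rep(1:2, each = 25), rownames(M))
  target <- "cg10"
  comp <- buildComponentMatrices(M, grouping, target, window_bp = 2500,
                                 positions = pos)
  # brute force: standardize, exclude, average outer products
  bruteA <- function(ids) {
    Zi <- t(apply(M[ids, , drop = FALSE], 1,
                  function(y) (y - mean(y)) / sd(y)))
    Reduce(`+`, lapply(seq_along(ids), function(i)
      tcrossprod(Zi[i, ]))) / length(ids)
  }
  excl <- pos$cpg_id[abs(pos$start - pos$start[10]) <= 2500]
  ids1 <- setdiff(names(grouping)[grouping == 1], excl)
  expect_lt(max(abs(comp$matrices$group1 - bruteA(ids1))), 1e-10)
  ids2 <- setdiff(names(grouping)[grouping == 2], excl)
  expect_lt(max(abs(comp$matrices$group2 - bruteA(ids2))), 1e-10)
  # PSD with trace ~ n
  ev <- eigen(comp$matrices$group1, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_equal(sum(diag(comp$matrices$group1)), n, tolerance = 0.05 * n)

  # zero window: only the target itself is excluded
  c0 <- buildComponentMatrices(M, grouping, target, window_bp = 0)
  expect_identical(c0$excluded, target)
  # a group holding only the target is dropped
  g1 <- setNames(c(1L, rep(2L, p - 1L)), c(target, setdiff(rownames(M), target)))
  cd <- buildComponentMatrices(M, g1, target, window_bp = 0)
  expect_identical(cd$dropped, "1")
})

test_that("identity-only components collapse the mixed test to OLS", {
  set.seed(85)
  n <- 100
  x <- rnorm(n); covs <- data.frame(z = rnorm(n))
  y <- 0.4 * x + rnorm(n)
  ft <- momentTestProbe(y, x, covariates = covs,
                        component_matrices = list(id = diag(n)))
  ols <- summary(lm(y ~ z + target, data = cbind(covs, target = x)))
  expect_lt(abs(ft$effect - ols$coefficients["target", 1]), 1e-8)
  expect_lt(abs(ft$se - ols$coefficients["target", 2]), 1e-8)
  expect_lt(abs(ft$p - ols$coefficients["target", 4]), 1e-8)
})

test_that("the two association engines agree on planted effect signs", {
  set.seed(86)
  agree <- vapply(1:20, function(r) {
    d <- cohortDesign(nIndividuals = 250, nCpgs = 120, nCausal = 1,
                      effectSize = 0.4, seed = 300 + r,
                      varFractions = noiseFractions, liabilityFamilial = 0)
    coh <- simulateCohort(d)
    cs <- causalSites(coh$truth, "brs")
    t1 <- runMwas1(coh$mset, coh$samples$brs, n_pcs = 0)
    t2 <- suppressWarnings(runMwas2(coh$mset, coh$samples$brs, n_pcs = 0,
                                    targets = cs$cpg_id))
    sign(t1$effect[match(cs$cpg_id, t1$cpg_id)]) == sign(t2$effect)
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})

test_that("approximate and exact modes agree and runs are deterministic", {
  d <- cohortDesign(nIndividuals = 150, nCpgs = 100, nCausal = 2, seed = 87)
  coh <- simulateCohort(d)
  targets <- rownames(mValues(coh$mset))[seq(1, 100, by = 20)]
  a <- suppressWarnings(runMwas2(coh$mset, coh$samples$brs, n_pcs = 5,
                                 window_bp = 3000, targets = targets))
  b <- suppressWarnings(runMwas2(coh$mset, coh$samples$brs, n_pcs = 5,
                                 window_bp = 3000, targets = targets,
                                 mode = "exact"))
  expect_lt(max(abs(a$effect - b$effect)), 0.05 * max(b$se))
  expect_lt(max(abs(log10(a$p) - log10(b$p))), 0.05)
  expect_identical(attr(a, "mode"), "approx")
  expect_identical(attr(b, "mode"), "exact")
  a2 <- suppressWarnings(runMwas2(coh$mset, coh$samples$brs, n_pcs = 5,
                                  window_bp = 3000, targets = targets))
  expect_identical(a, a2)
})

test_that("m = 1 grouping reduces the engine to a single-component model", {
  set.seed(88)
  d <- cohortDesign(nIndividuals = 120, nCpgs = 60, nCausal = 0, seed = 89,
                    varFractions = noiseFractions)
  coh <- simulateCohort(d)
  t_m1 <- runMwas2(coh$mset, rnorm(120), n_pcs = 0, m = 1,
                   targets = rownames(mValues(coh$mset))[1:10])
  expect_true(all(is.finite(t_m1$p)))
  expect_equal(nrow(t_m1), 10)
})
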