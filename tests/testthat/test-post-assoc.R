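test_that("Bonferroni thresholds reproduce the printed values", {
  expect_equal(signif(bonferroniThreshold(0.05, 713522), 3), 7.01e-8)
  expect_equal(bonferroniThreshold(0.05, 8), 6.25e-3)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_error(bonferroniThreshold(0.05, 0), ">= 1")
  # monotone decreasing in the number of tests
  thr <- bonferroniThreshold(0.05, c(1, 10, 100, 1e6))
  expect_false(is.unsorted(rev(thr)))
})

test_that("genomic inflation matches chi-squared quantile ratios", {
  expect_equal(genomicInflation(rep(0.5, 100))$lambda, 1)
  expect_equal(round(genomicInflation(rep(0.05, 10))$lambda, 3),
               round(qchisq(0.05, 1, lower.tail = FALSE) / qchisq(0.5, 1), 3))
  expect_equal(round(genomicInflation(rep(0.05, 10))$lambda, 3), 8.444)
  set.seed(91)
  p <- runif(1e5)
  lam <- genomicInflation(p)$lambda
  expect_gt(lam, 0.98); expect_lt(lam, 1.02)
  # permutation invariance
  expect_identical(genomicInflation(p)$lambda,
                   genomicInflation(sample(p))$lambda)
  expect_error(genomicInflation(numeric(0)), "no valid")
  expect_error(genomicInflation(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("QQ coordinates use order-statistic expectations with a beta band", {
  q1 <- qqPoints(0.2)
  expect_equal(q1$expected, -log10(0.5), tolerance = 1e-12)
  expect_equal(q1$observed, -log10(0.2))
  set.seed(92)
  qq <- qqPoints(runif(2000))
  expect_false(is.unsorted(qq$expected))
  expect_false(is.unsorted(qq$observed))
  inside <- mean(qq$observed >= qq$lower & qq$observed <= qq$upper)
  expect_gt(inside, 0.85)
})

test_that("Miami export keeps the probe universe with signed log scales", {
  t1 <- data.frame(cpg_id = c("a", "b", "c"), chrom = "chr1",
                   pos = c(100, 200, 300),
                   p = c(7.01e-8, 0.5, 0.01))
  t2 <- data.frame(cpg_id = c("a", "b", "d"), chrom = c("chr1", "chr1", "chr2"),
                   pos = c(100, 200, 50), p = c(1e-3, 0.2, 0.9))
  mi <- miamiExport(t1, t2, threshold = 7.01e-8)
  expect_equal(nrow(mi), 4)                       # union of probes
  expect_equal(mi$log10p_mwas1[mi$cpg_id == "a"], log10(7.01e-8))
  expect_equal(mi$log10p_mwas1[mi$cpg_id == "a"],
               mi$sig_line_mwas1[1])              # sits exactly on the line
  expect_true(is.na(mi$neglog10p_mwas2[mi$cpg_id == "c"]))
  expect_true(is.na(mi$log10p_mwas1[mi$cpg_id == "d"]))
  expect_true(all(mi$log10p_mwas1 <= 0, na.rm = TRUE))
  expect_true(all(mi$neglog10p_mwas2 >= 0, na.rm = TRUE))
})

test_that("significant-site annotation and overlap behave on toy tables", {
  tab <- data.frame(cpg_id = c("c1", "c2", "c3", "c4"),
                    p = c(1e-9, 1e-9, 1e-9, 0.5))
  ann <- data.frame(cpg_id = c("c1", "c2", "c3", "c4"),
                    gene = c("A", "A", NA, "B"))
  out <- annotateSignificant(tab, ann, threshold = 7.01e-8)
  expect_identical(out$genes, "A")
  expect_identical(out$unannotated, "c3")
  expect_length(annotateSignificant(
    data.frame(cpg_id = "c1", p = 0.9), ann)$genes, 0)
  expect_length(geneOverlap(c("A", "B"), c("C", "D")), 0)
  expect_identical(geneOverlap(c("A", "B"), c("B", "C")), "B")
})

test_that("equal probe counts reduce enrichment to the hypergeometric tail", {
  set.seed(93)
  genes <- sprintf("G%03d", 1:100)
  ann <- data.frame(cpg_id = sprintf("cg%03d", 1:300),
                    gene = rep(genes, each = 3))   # equal counts
  sets <- list(s1 = genes[1:20], s2 = genes[21:90], s3 = c("ZZZ"))
  sig <- ann$cpg_id[ann$gene %in% genes[c(1:8, 30:35)]]
  res <- genesetEnrichment(sig, ann$cpg_id, ann, sets)
  n_sig <- 14
  expect_equal(res$p[1],
               phyper(sum(genes[1:8] %in% genes[1:20]) - 1, 20, 80, n_sig,
                      lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(is.na(res$p[3]))                    # no annotated genes
  # empty significant set: every P = 1
  res0 <- genesetEnrichment(character(), ann$cpg_id, ann, sets[1:2])
  expect_true(all(res0$p == 1))
})

test_that("probe-count bias is corrected where the naive test inflates", {
  set.seed(94)
  n_genes <- 200
  genes <- sprintf("G%03d", 1:n_genes)
  counts <- rep(c(1L, 10L), each = n_genes / 2)   # strong probe-count bias
  ann <- data.frame(
    cpg_id = sprintf("cg%05d", seq_len(sum(counts))),
    gene = rep(genes, counts))
  reps <- 400
  p_corr <- p_naive <- numeric(reps)
  for (r in seq_len(reps)) {
    sig <- sample(ann$cpg_id, 60)                 # uniform over probes
    sig_genes <- unique(ann$gene[ann$cpg_id %in% sig])
    # null set, but biased toward probe-rich genes (as real gene sets are)
    set_r <- sample(genes, 40, prob = counts)
    res <- genesetEnrichment(sig, ann$cpg_id, ann, list(s = set_r))
    p_corr[r] <- res$p
    x <- length(intersect(sig_genes, set_r))
    p_naive[r] <- phyper(x - 1, 40, n_genes - 40, length(sig_genes),
                         lower.tail = FALSE)
  }
  t1_corr <- mean(p_corr < 0.05)
  t1_naive <- mean(p_naive < 0.05)
  expect_gt(t1_corr, 0.03); expect_lt(t1_corr, 0.07)
  expect_gt(t1_naive, 0.10)
})
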