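#' Principal components of the methylome
#'
#' Top-`k` principal-component scores of the sample-by-CpG matrix (each CpG
#' centred). Signs follow a deterministic convention: the
#' largest-magnitude CpG loading of each component is made positive.
#'
#' @param x an [MValueSet-class] or a CpG-by-sample matrix.
#' @param k number of components.
#' @return numeric matrix, samples x `k`, columns `PC1..PCk`.
#' @export
computeMethylomePCs <- function(x, k = 20L) {
  M <- if (is(x, "MValueSet")) mValues(x) else as.matrix(x)
  Xc <- t(M - rowMeans(M))                 # samples x CpGs, CpGs centred
  n <- nrow(Xc)
  if (k > min(dim(Xc))) stop("k exceeds matrix rank limit min(dims) = ",
                             min(dim(Xc)))
  G <- tcrossprod(Xc)
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  if (k > sum(pos)) stop("k = ", k, " exceeds matrix rank ", sum(pos))
  d <- sqrt(e$values[seq_len(k)])
  U <- e$vectors[, seq_len(k), drop = FALSE]
  scores <- U * rep(d, each = n)
  loadings <- crossprod(Xc, U) / rep(d, each = ncol(Xc))
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(M), paste0("PC", seq_len(k)))
  scores
}

#' Probewise ordinary least squares
#'
#' Fits, per CpG, `M ~ phenotype + covariates` (one shared design), the
#' M-values being the dependent variable. Binary phenotypes are coded 0/1;
#' continuous phenotypes should be standardized beforehand so effects are
#' per-SD (see [runMwas1()], which does this).
#'
#' @param M CpG-by-sample matrix (complete-case aligned with the phenotype).
#' @param phenotype numeric vector.
#' @param covariates data.frame/matrix of adjustment covariates or `NULL`.
#' @return data.frame: `cpg_id`, `effect`, `se`, `sigma2` (residual
#'   variance), `df`, `n`.
#' @export
fitProbewise <- function(M, phenotype, covariates = NULL) {
  n <- ncol(M)
  stopifnot(length(phenotype) == n)
  dfr <- data.frame(phenotype = phenotype)
  if (!is.null(covariates)) dfr <- cbind(dfr, as.data.frame(covariates))
  X <- buildDesign(dfr)
  qr_X <- qr(X)
  Y <- t(M)
  B <- qr.coef(qr_X, Y)
  E <- qr.resid(qr_X, Y)
  dfres <- n - ncol(X)
  s2 <- colSums(E^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- match("phenotype", colnames(X))
  XtXinv_ph <- XtXinv[j, j]
  data.frame(cpg_id = rownames(M),
             effect = unname(B["phenotype", ]),
             se = sqrt(s2 * XtXinv_ph),
             sigma2 = unname(s2), df = dfres, n = n,
             stringsAsFactors = FALSE)
}

# Invert the (monotone decreasing) trigamma function by bisection.
trigammaInverse <- function(t, tol = 1e-8) {
  vapply(t, function(ti) {
    if (ti <= 0) return(Inf)
    lo <- 1e-8; hi <- 1e8
    if (trigamma(lo) < ti) return(lo)
    if (trigamma(hi) > ti) return(hi)
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > ti) lo <- mid else hi <- mid
      if (hi - lo < tol * lo) break
    }
    sqrt(lo * hi)
  }, 1.0)
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the scaled-F prior (`d0`, `s0^2`) by matching the first two
#' moments of the log residual variances, then shrinks each variance to
#' `(d0 * s0^2 + df * s^2) / (d0 + df)`. When the log-variances are no more
#' dispersed than sampling alone explains, `d0 = Inf` and every posterior
#' variance equals `s0^2`; forcing `d0 = 0` disables shrinkage.
#'
#' @param sigma2 per-probe residual variances.
#' @param df residual degrees of freedom (scalar or per-probe).
#' @param d0 optional forced prior df (overrides estimation).
#' @return list: `d0`, `s02`, `posterior` (per-probe variances).
#' @export
moderateVariances <- function(sigma2, df, d0 = NULL) {
  if (length(sigma2) < 10 && is.null(d0))
    stop("need at least 10 probes to estimate the variance prior")
  df <- rep_len(df, length(sigma2))
  if (any(sigma2 <= 0)) stop("residual variances must be positive")
  e <- log(sigma2) - digamma(df / 2) + log(df / 2)
  if (is.null(d0)) {
    evar <- var(e) - mean(trigamma(df / 2))
    d0 <- if (evar <= 0) Inf else 2 * trigammaInverse(evar)
  }
  s02 <- if (is.infinite(d0)) exp(mean(e)) else if (d0 == 0) NA_real_ else
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  posterior <- if (is.infinite(d0)) rep(s02, length(sigma2)) else
    if (d0 == 0) sigma2 else (d0 * s02 + df * sigma2) / (d0 + df)
  list(d0 = d0, s02 = s02, posterior = posterior)
}

#' Moderated t-tests from probewise fits
#'
#' Rescales each standard error by the shrunken residual variance and
#' tests `t = effect / se_mod` against a t distribution with `df + d0`
#' degrees of freedom (two-sided). With `d0 = 0` this reproduces ordinary
#' OLS t-tests exactly.
#'
#' @param fits output of [fitProbewise()].
#' @param moderation output of [moderateVariances()].
#' @return data.frame: `cpg_id`, `effect`, `se`, `stat`, `p`, `n`.
#' @export
moderatedTTest <- function(fits, moderation) {
  se_mod <- fits$se * sqrt(moderation$posterior / fits$sigma2)
  tstat <- fits$effect / se_mod
  dft <- fits$df + moderation$d0
  p <- 2 * pt(-abs(tstat), df = dft)
  data.frame(cpg_id = fits$cpg_id, effect = fits$effect, se = se_mod,
             stat = tstat, p = p, n = fits$n, stringsAsFactors = FALSE)
}

#' Run the moderated probewise association engine (MWAS 1)
#'
#' Per-CpG linear model with the M-values as dependent variable and the
#' phenotype as independent variable, adjusted for measurement set,
#' smoking status, pack years and the first `n_pcs` principal components of
#' the corrected methylome, with empirical-Bayes variance moderation.
#' Continuous phenotypes are standardized so effects are per SD; binary
#' phenotypes enter as 0/1.
#'
#' @param mset an [MValueSet-class] (corrected M-values).
#' @param phenotype numeric vector aligned to samples (`NA` allowed;
#'   complete-case analysis).
#' @param covariates data.frame of adjustment covariates; defaults to
#'   `set`, `smoking_status`, `pack_years` from `colData` when present.
#' @param n_pcs number of methylome PCs fitted as fixed effects.
#' @param d0 optional forced prior df for moderation.
#' @return association table: `cpg_id`, `chrom`, `pos`, `effect`, `se`,
#'   `stat`, `p`, `n`, `engine`.
#' @export
runMwas1 <- function(mset, phenotype, covariates = NULL, n_pcs = 20L,
                     d0 = NULL) {
  M <- mValues(mset)
  stopifnot(length(phenotype) == ncol(M))
  if (is.null(covariates)) {
    cd <- as.data.frame(SummarizedExperiment::colData(mset))
    covariates <- cd[, intersect(c("set", "smoking_status", "pack_years"),
                                 names(cd)), drop = FALSE]
  }
  keep <- !is.na(phenotype) &
    (if (length(covariates)) complete.cases(covariates) else TRUE)
  M <- M[, keep, drop = FALSE]
  phen <- phenotype[keep]
  cov_cc <- if (length(covariates))
    as.data.frame(covariates)[keep, , drop = FALSE] else NULL
  if (length(unique(phen)) > 2L) phen <- zscore(phen)
  if (n_pcs > 0L) {
    pcs <- computeMethylomePCs(M, k = n_pcs)
    cov_cc <- if (is.null(cov_cc)) as.data.frame(pcs) else
      cbind(cov_cc, as.data.frame(pcs))
  }
  fits <- fitProbewise(M, phen, cov_cc)
  mod <- moderateVariances(fits$sigma2, fits$df, d0 = d0)
  res <- moderatedTTest(fits, mod)
  pos <- cpgPositions(mset)
  idx <- match(res$cpg_id, pos$cpg_id)
  data.frame(cpg_id = res$cpg_id, chrom = pos$chrom[idx],
             pos = pos$start[idx], effect = res$effect, se = res$se,
             stat = res$stat, p = res$p, n = res$n, engine = "mwas1",
             stringsAsFactors = FALSE)
}
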