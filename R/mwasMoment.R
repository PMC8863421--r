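#' Initial marginal scan (phenotype as dependent variable)
#'
#' Per-probe linear regression of the phenotype on each probe's M-values
#' plus covariates, used to group probes before the multi-component fit.
#' Computed by residualizing phenotype and probes on the covariate design,
#' so the per-probe t statistic equals the probewise-OLS t under exchanged
#' roles when both variables are standardized.
#'
#' @param M CpG-by-sample matrix.
#' @param phenotype numeric vector (complete cases only).
#' @param covariates data.frame/matrix or `NULL`.
#' @return data.frame: `cpg_id`, `effect`, `se`, `stat`, `p`.
#' @export
initialScan <- function(M, phenotype, covariates = NULL) {
  n <- ncol(M)
  stopifnot(length(phenotype) == n)
  X <- buildDesign(if (is.null(covariates)) data.frame(row.names = seq_len(n))
                   else as.data.frame(covariates))
  qr_X <- qr(X)
  yr <- qr.resid(qr_X, phenotype)
  Mr <- t(qr.resid(qr_X, t(M)))
  sxx <- rowSums(Mr^2)
  sxy <- drop(Mr %*% yr)
  beta <- sxy / sxx
  dfres <- n - ncol(X) - 1L
  rss <- sum(yr^2) - beta * sxy
  s2 <- rss / dfres
  se <- sqrt(s2 / sxx)
  stat <- beta / se
  data.frame(cpg_id = rownames(M), effect = beta, se = se, stat = stat,
             p = 2 * pt(-abs(stat), dfres), stringsAsFactors = FALSE)
}

#' Group probes from scan statistics
#'
#' Bins probes into `m` groups by P-value cut-points (default two groups
#' split at P < 0.05). Groups emptied by the cuts are merged with their
#' neighbour with a warning; `m = 1` yields the single-component model.
#'
#' @param scan_stats output of [initialScan()].
#' @param m number of components.
#' @param p_cuts increasing vector of `m - 1` P-value cut-points.
#' @return named integer vector of group labels (1 = most significant).
#' @export
groupProbes <- function(scan_stats, m = 2L, p_cuts = 0.05) {
  if (m == 1L)
    return(setNames(rep(1L, nrow(scan_stats)), scan_stats$cpg_id))
  stopifnot(length(p_cuts) == m - 1L, !is.unsorted(p_cuts))
  g <- findInterval(scan_stats$p, c(0, p_cuts, 1.000001))
  g <- pmin(g, m)
  tab <- tabulate(g, m)
  if (any(tab == 0L)) {
    warning("empty probe group(s) merged with neighbour")
    keep <- which(tab > 0L)
    g <- match(g, keep)
    g[is.na(g)] <- vapply(which(is.na(match(seq_len(m), keep))), function(e)
      keep[which.min(abs(keep - e))], 1L)[1]
    g <- as.integer(factor(g))
  }
  setNames(as.integer(g), scan_stats$cpg_id)
}

# Row-standardize a probe matrix (mean 0, sample-SD 1 per probe); constant
# probes are zeroed.
standardizeProbes <- function(M) {
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (ncol(M) - 1))
  Z <- (M - mu) / ifelse(s > 0, s, Inf)
  Z
}

#' Methylome relationship matrices per probe group, excluding the target
#'
#' For each group `g`, computes `A_g = Z_g' Z_g / p_g` over the group's
#' standardized probes after removing the target probe and every probe
#' within `window_bp` of it on the same chromosome. Groups emptied by the
#' exclusion are dropped (flagged in the result).
#'
#' @param M CpG-by-sample matrix.
#' @param grouping named group labels from [groupProbes()].
#' @param target target CpG id.
#' @param window_bp exclusion window around the target (0 = target only).
#' @param positions data.frame `cpg_id`, `chrom`, `start` (needed when
#'   `window_bp > 0`).
#' @return list: `matrices` (named list of n x n PSD matrices), `dropped`
#'   (labels of emptied groups), `excluded` (excluded probe ids).
#' @export
buildComponentMatrices <- function(M, grouping, target, window_bp = 50000,
                                   positions = NULL) {
  stopifnot(target %in% rownames(M))
  excl <- target
  if (window_bp > 0) {
    if (is.null(positions)) stop("positions needed for a nonzero window")
    pt <- positions[match(target, positions$cpg_id), ]
    near <- positions$cpg_id[positions$chrom == pt$chrom &
                               abs(positions$start - pt$start) <= window_bp]
    excl <- union(excl, near)
  }
  Z <- standardizeProbes(M)
  mats <- list(); dropped <- character()
  for (g in sort(unique(grouping))) {
    ids <- names(grouping)[grouping == g]
    use <- setdiff(ids, excl)
    if (!length(use)) { dropped <- c(dropped, as.character(g)); next }
    mats[[paste0("group", g)]] <- crossprod(Z[use, , drop = FALSE]) / length(use)
  }
  list(matrices = mats, dropped = dropped,
       excluded = intersect(excl, rownames(M)))
}

#' Multi-component mixed-model test of one target probe
#'
#' REML fit of the phenotype on the group relationship matrices (random
#' effects) with covariates, blood cell counts and the target probe's
#' M-values as fixed effects, followed by a generalized-least-squares Wald
#' test of the target coefficient. Binary phenotypes are analysed on the
#' 0/1 scale in the linear mixed model.
#'
#' @param phenotype numeric response.
#' @param target_mvalues the target probe's M-values.
#' @param covariates data.frame of fixed covariates or `NULL`.
#' @param cell_counts matrix/data.frame of blood cell counts fitted as
#'   fixed effects, or `NULL`.
#' @param component_matrices named list of n x n covariance structures.
#' @param tol,maxit REML controls.
#' @return list: `effect`, `se`, `stat`, `p`, `sigma2`, `converged`.
#' @export
momentTestProbe <- function(phenotype, target_mvalues, covariates = NULL,
                            cell_counts = NULL, component_matrices,
                            tol = 1e-6, maxit = 50L) {
  n <- length(phenotype)
  covdf <- if (is.null(covariates)) data.frame(row.names = seq_len(n))
           else as.data.frame(covariates)
  if (!is.null(cell_counts)) covdf <- cbind(covdf, as.data.frame(cell_counts))
  covdf$target <- target_mvalues
  X <- buildDesign(covdf)
  fit <- tryCatch(aiREML(phenotype, X, component_matrices,
                         tol = tol, maxit = maxit),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(list(effect = NA_real_, se = NA_real_, stat = NA_real_,
                p = NA_real_, sigma2 = NULL, converged = FALSE))
  }
  j <- which(colnames(X) == "target")
  stat <- fit$beta[j] / fit$beta_se[j]
  list(effect = unname(fit$beta[j]), se = unname(fit$beta_se[j]),
       stat = unname(stat),
       p = 2 * pt(-abs(stat), df = n - ncol(X)),
       sigma2 = fit$sigma2, converged = TRUE)
}

#' Run the multi-component association engine (MWAS 2)
#'
#' Full procedure: marginal scan with the phenotype as dependent variable,
#' probe grouping by scan P-values, then a per-target mixed-model test with
#' the grouped probes as random effects (the target and its `window_bp`
#' neighbourhood excluded from the components) and blood cell counts as
#' fixed effects.
#'
#' Two modes: `"exact"` re-estimates the variance components for every
#' target (per-target REML, expensive); `"approx"` estimates them once from
#' the target-free model, freezes them, and applies the per-target probe
#' exclusion as a low-rank Woodbury downdate of the covariance (divisors
#' kept at the full group sizes). The mode is recorded in the output.
#'
#' @param mset an [MValueSet-class].
#' @param phenotype numeric vector aligned to samples (`NA` allowed).
#' @param covariates data.frame of adjustment covariates; defaults as in
#'   [runMwas1()] plus `n_pcs` methylome PCs.
#' @param cell_counts matrix of blood cell counts; defaults to the
#'   `basophil..neutrophil` columns of `colData` when present.
#' @param m number of probe groups.
#' @param p_cuts scan P cut-points (length `m - 1`); default `NULL` splits
#'   lead sites from the rest at the Bonferroni-corrected scan threshold
#'   `0.05 / n_probes` (under a null phenotype the lead group is then
#'   empty and the model collapses to a single whole-methylome component,
#'   which keeps the engine calibrated; a lenient cut such as 0.05 lets
#'   the random effect absorb chance phenotype-probe correlations and
#'   deflates the test).
#' @param window_bp exclusion window around each target, base pairs.
#' @param n_pcs methylome PCs included in the scan covariates.
#' @param mode `"approx"` or `"exact"`.
#' @param targets optional subset of CpG ids to test (default: all).
#' @return association table: `cpg_id`, `chrom`, `pos`, `effect`, `se`,
#'   `stat`, `p`, `n`, `engine`; attribute `mode` records the fitting mode.
#' @export
runMwas2 <- function(mset, phenotype, covariates = NULL, cell_counts = NULL,
                     m = 2L, p_cuts = NULL, window_bp = 50000, n_pcs = 20L,
                     mode = c("approx", "exact"), targets = NULL) {
  mode <- match.arg(mode)
  M <- mValues(mset)
  if (is.null(p_cuts)) p_cuts <- rep(0.05 / nrow(M), m - 1L)
  cd <- as.data.frame(SummarizedExperiment::colData(mset))
  if (is.null(covariates))
    covariates <- cd[, intersect(c("set", "smoking_status", "pack_years"),
                                 names(cd)), drop = FALSE]
  cellcols <- c("basophil", "eosinophil", "lymphocyte", "monocyte",
                "neutrophil")
  if (is.null(cell_counts) && all(cellcols %in% names(cd)))
    cell_counts <- as.matrix(cd[, cellcols])
  keep <- !is.na(phenotype) &
    (if (length(covariates)) complete.cases(covariates) else TRUE)
  M <- M[, keep, drop = FALSE]
  phen <- phenotype[keep]
  if (length(unique(phen)) > 2L) phen <- zscore(phen)
  covs <- if (length(covariates))
    as.data.frame(covariates)[keep, , drop = FALSE] else NULL
  cells <- if (!is.null(cell_counts))
    as.matrix(cell_counts)[keep, , drop = FALSE] else NULL
  if (n_pcs > 0L) {
    pcs <- computeMethylomePCs(M, k = n_pcs)
    covs <- if (is.null(covs)) as.data.frame(pcs) else
      cbind(covs, as.data.frame(pcs))
  }
  positions <- cpgPositions(mset)

  scan <- initialScan(M, phen, covs)
  grouping <- groupProbes(scan, m = m, p_cuts = p_cuts)
  if (is.null(targets)) targets <- rownames(M)

  res <- if (mode == "approx") {
    mwas2Approx(M, phen, covs, cells, grouping, targets, window_bp, positions)
  } else {
    mwas2Exact(M, phen, covs, cells, grouping, targets, window_bp, positions)
  }
  idx <- match(res$cpg_id, positions$cpg_id)
  out <- data.frame(cpg_id = res$cpg_id, chrom = positions$chrom[idx],
                    pos = positions$start[idx], effect = res$effect,
                    se = res$se, stat = res$stat, p = res$p,
                    n = ncol(M), engine = "mwas2", stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

# Exact mode: per-target component rebuild + REML.
mwas2Exact <- function(M, phen, covs, cells, grouping, targets, window_bp,
                       positions) {
  out <- lapply(targets, function(tg) {
    comp <- buildComponentMatrices(M, grouping, tg, window_bp, positions)
    if (!length(comp$matrices))
      return(data.frame(cpg_id = tg, effect = NA, se = NA, stat = NA, p = NA))
    ft <- momentTestProbe(phen, M[tg, ], covs, cells, comp$matrices)
    data.frame(cpg_id = tg, effect = ft$effect, se = ft$se, stat = ft$stat,
               p = ft$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Approximate mode: one REML fit of the target-free multi-component model,
# frozen variance components, per-target Woodbury downdate for the
# excluded probes, then GLS Wald tests.
mwas2Approx <- function(M, phen, covs, cells, grouping, targets, window_bp,
                        positions) {
  n <- ncol(M)
  covdf <- if (is.null(covs)) data.frame(row.names = seq_len(n)) else covs
  if (!is.null(cells)) covdf <- cbind(covdf, as.data.frame(cells))
  X0 <- buildDesign(covdf)
  Z <- standardizeProbes(M)
  glabs <- sort(unique(grouping))
  psize <- vapply(glabs, function(g) sum(grouping == g), 1L)
  Alist <- lapply(glabs, function(g)
    crossprod(Z[names(grouping)[grouping == g], , drop = FALSE]) /
      sum(grouping == g))
  names(Alist) <- paste0("group", glabs)
  fit <- aiREML(phen, X0, Alist)
  s_g <- fit$sigma2[seq_along(Alist)]
  V <- diag(rep(fit$sigma2[["residual"]], n))
  for (k in seq_along(Alist)) V <- V + s_g[k] * Alist[[k]]
  Vinv <- chol2inv(chol(V))
  ViZt <- Vinv %*% t(Z)                # n x p, columns are Vinv z_i
  ViX0 <- Vinv %*% X0
  Viy <- drop(Vinv %*% phen)
  Vi1 <- rowSums(Vinv)
  dscale <- setNames(s_g / psize, as.character(glabs))
  mu <- rowMeans(M)
  sdv <- sqrt(rowSums((M - mu)^2) / (n - 1))
  p0 <- ncol(X0)
  dfres <- n - p0 - 1L

  chrs <- positions$chrom[match(rownames(M), positions$cpg_id)]
  starts <- positions$start[match(rownames(M), positions$cpg_id)]
  rows <- vector("list", length(targets))
  for (ii in seq_along(targets)) {
    tg <- targets[ii]
    ti <- match(tg, rownames(M))
    ex <- ti
    if (window_bp > 0)
      ex <- which(chrs == chrs[ti] & abs(starts - starts[ti]) <= window_bp)
    ex <- ex[sdv[ex] > 0]              # constant probes contribute nothing
    d <- dscale[as.character(grouping[rownames(M)[ex]])]
    usable <- d > 0
    ex <- ex[usable]; d <- d[usable]
    # target column of the fixed design on the original M scale
    xt <- M[ti, ]
    Vixt <- if (sdv[ti] > 0) sdv[ti] * ViZt[, ti] + mu[ti] * Vi1 else
      mu[ti] * Vi1
    if (length(ex)) {
      U <- t(Z[ex, , drop = FALSE])                   # n x k
      W <- ViZt[, ex, drop = FALSE]                   # Vinv U
      Mid <- solve(diag(1 / d, length(d)) - crossprod(U, W))
      corr <- function(a, Via) Via + W %*% (Mid %*% crossprod(W, a))
      Vty <- corr(phen, Viy)
      VtX0 <- corr(X0, ViX0)
      Vtxt <- corr(xt, Vixt)
    } else {
      Vty <- Viy; VtX0 <- ViX0; Vtxt <- Vixt
    }
    XtVX <- rbind(cbind(crossprod(X0, VtX0), crossprod(X0, Vtxt)),
                  c(crossprod(xt, VtX0), sum(xt * Vtxt)))
    XtVy <- c(crossprod(X0, Vty), sum(xt * Vty))
    cv <- tryCatch(chol2inv(chol(XtVX)), error = function(e) NULL)
    if (is.null(cv)) {
      rows[[ii]] <- data.frame(cpg_id = tg, effect = NA_real_, se = NA_real_,
                               stat = NA_real_, p = NA_real_)
      next
    }
    beta <- drop(cv %*% XtVy)
    j <- length(beta)
    se <- sqrt(cv[j, j])
    stat <- beta[j] / se
    rows[[ii]] <- data.frame(cpg_id = tg, effect = beta[j], se = se,
                             stat = stat, p = 2 * pt(-abs(stat), dfres),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
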