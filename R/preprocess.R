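#' Quality-control thresholds
#'
#' Bundles the QC cut-offs with their boundary conventions: samples are
#' removed when the fraction of probes with detection P > `detection_p`
#' is `>=` `sample_fail_frac` (inclusive); probes are removed when the
#' beadcount is `<` `beadcount_min` in strictly more than
#' `beadcount_fail_frac` of samples, or when `>=` `probe_fail_frac` of
#' samples fail detection.
#'
#' @param sample_fail_frac sample-level failing-probe fraction limit (0.01).
#' @param probe_fail_frac probe-level failing-sample fraction limit (0.005).
#' @param beadcount_fail_frac fraction of samples allowed below the
#'   beadcount minimum (0.05).
#' @param beadcount_min minimum beadcount (3).
#' @param detection_p detection P-value cut-off (0.05).
#' @param exclude_probes character vector of probe ids to drop outright
#'   (cross-reactive / polymorphic sites).
#' @return list of class `qc_thresholds`.
#' @export
qcThresholds <- function(sample_fail_frac = 0.01, probe_fail_frac = 0.005,
                         beadcount_fail_frac = 0.05, beadcount_min = 3,
                         detection_p = 0.05, exclude_probes = character()) {
  fr <- c(sample_fail_frac, probe_fail_frac, beadcount_fail_frac, detection_p)
  if (any(fr < 0 | fr > 1)) stop("QC fractions must lie in [0, 1]")
  structure(list(sample_fail_frac = sample_fail_frac,
                 probe_fail_frac = probe_fail_frac,
                 beadcount_fail_frac = beadcount_fail_frac,
                 beadcount_min = beadcount_min,
                 detection_p = detection_p,
                 exclude_probes = exclude_probes),
            class = "qc_thresholds")
}

#' Compute M-values from probe intensities
#'
#' `M = log2((meth + offset) / (unmeth + offset))`, the log2 ratio of
#' methylated to unmethylated probe intensity. The default offset of 0 is
#' appropriate when all intensities are positive.
#'
#' @param meth,unmeth non-negative intensity matrices of equal dimension
#'   (CpGs x samples).
#' @param offset added to both channels before the ratio.
#' @param positions optional position table to build an [MValueSet-class];
#'   when omitted the bare matrix is returned.
#' @return matrix of M-values, or an [MValueSet-class] when `positions`
#'   is given.
#' @examples
#' computeMValues(matrix(4), matrix(1))   # log2(4) = 2
#' @export
computeMValues <- function(meth, unmeth, offset = 0, positions = NULL) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  if (!identical(dim(meth), dim(unmeth)))
    stop("meth and unmeth dimensions differ")
  if (any(meth < 0) || any(unmeth < 0)) stop("intensities must be >= 0")
  if (offset == 0 && (any(unmeth == 0) || any(meth == 0)))
    stop("zero intensities present: set a positive offset ",
         "(e.g. offset = 1) to compute finite M-values")
  M <- log2((meth + offset) / (unmeth + offset))
  if (is.null(positions)) return(M)
  MValueSet(M, positions, stage = "raw")
}

#' Convert beta-values to M-values
#' @param beta methylation fractions in (0, 1).
#' @return `log2(beta / (1 - beta))`.
#' @export
betaToM <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta values must lie strictly in (0, 1)")
  log2(beta / (1 - beta))
}

#' Sample-level quality control
#'
#' Removes samples whose fraction of failing probes (detection
#' P > cut-off) is at or above the limit, samples whose methylation-predicted
#' sex mismatches the recorded sex, and samples on a supplied
#' multidimensional-scaling outlier list (outlier detection itself is
#' delegated to the caller).
#'
#' @param mset an [MValueSet-class].
#' @param detection_p matrix of detection P-values aligned with `mset`.
#' @param predicted_sex,recorded_sex per-sample sex codes (any consistent
#'   coding); `NULL` skips the check.
#' @param mds_outliers character vector of sample ids to drop.
#' @param thresholds a [qcThresholds()] list.
#' @return list: `mset` (filtered) and `report` (removals by reason).
#' @export
filterSamples <- function(mset, detection_p, predicted_sex = NULL,
                          recorded_sex = NULL, mds_outliers = character(),
                          thresholds = qcThresholds()) {
  M <- mValues(mset)
  if (!identical(dim(detection_p), dim(M)))
    stop("detection P matrix is not aligned with the M-value matrix")
  fail_frac <- colMeans(detection_p > thresholds$detection_p)
  by_det <- colnames(M)[fail_frac >= thresholds$sample_fail_frac]
  by_sex <- character()
  if (!is.null(predicted_sex) && !is.null(recorded_sex)) {
    if (length(predicted_sex) != ncol(M) || length(recorded_sex) != ncol(M))
      stop("sex vectors are not aligned with samples")
    mism <- !is.na(predicted_sex) & !is.na(recorded_sex) &
      predicted_sex != recorded_sex
    by_sex <- colnames(M)[mism]
  }
  by_mds <- intersect(mds_outliers, colnames(M))
  drop <- unique(c(by_det, by_sex, by_mds))
  keep <- setdiff(colnames(M), drop)
  report <- list(samples_removed = list(detection = by_det, sex_mismatch = by_sex,
                                        mds_outlier = by_mds),
                 n_removed = length(drop), n_retained = length(keep),
                 n_input = ncol(M))
  list(mset = mset[, keep], report = report)
}

#' Probe-level quality control
#'
#' Removes probes where (i) the beadcount is below the minimum in strictly
#' more than the allowed fraction of samples, (ii) at least the allowed
#' fraction of samples fail detection, or (iii) the probe is on the
#' supplied exclusion list (non-specific binding / polymorphic sites).
#' Rules are independent, so their application order does not matter.
#'
#' @param mset an [MValueSet-class].
#' @param beadcount integer matrix aligned with `mset`, or `NULL` to skip.
#' @param detection_p detection P matrix aligned with `mset`, or `NULL`.
#' @param thresholds a [qcThresholds()] list.
#' @return list: `mset` (filtered) and `report`.
#' @export
filterProbes <- function(mset, beadcount = NULL, detection_p = NULL,
                         thresholds = qcThresholds()) {
  M <- mValues(mset)
  by_bead <- by_det <- character()
  if (!is.null(beadcount)) {
    if (!identical(dim(beadcount), dim(M)))
      stop("beadcount matrix is not aligned")
    frac <- rowMeans(beadcount < thresholds$beadcount_min)
    by_bead <- rownames(M)[frac > thresholds$beadcount_fail_frac]
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(M)))
      stop("detection P matrix is not aligned")
    frac <- rowMeans(detection_p > thresholds$detection_p)
    by_det <- rownames(M)[frac >= thresholds$probe_fail_frac]
  }
  by_list <- intersect(thresholds$exclude_probes, rownames(M))
  drop <- unique(c(by_bead, by_det, by_list))
  keep <- setdiff(rownames(M), drop)
  report <- list(probes_removed = list(beadcount = by_bead, detection = by_det,
                                       exclusion_list = by_list),
                 n_removed = length(drop), n_retained = length(keep),
                 n_input = nrow(M))
  list(mset = mset[keep, ], report = report)
}

#' Stage-1 correction: technical variation
#'
#' Fits, per CpG, a linear mixed model with plate and blood-draw date as
#' crossed random intercepts and the supplied technical covariates (plate
#' position, measurement set, clinic, appointment year and weekday, control
#' principal components, ...) as fixed effects, and returns the residuals.
#' By Henderson's mixed-model equations the residuals are exactly
#' orthogonal to every fixed-design column; the intercept is removed with
#' the fixed effects, so residuals are centred.
#'
#' @param mset an [MValueSet-class].
#' @param fixed data.frame of fixed covariates (factors and numerics),
#'   one row per sample; an intercept is added.
#' @param plate,date per-sample grouping factors for the two random
#'   intercepts (defaults read from `colData`).
#' @return An [MValueSet-class] at stage `technical`, with per-CpG variance
#'   estimates in `rowData`.
#' @export
correctTechnical <- function(mset, fixed,
                             plate = SummarizedExperiment::colData(mset)$plate,
                             date = SummarizedExperiment::colData(mset)$draw_date) {
  M <- mValues(mset)
  n <- ncol(M)
  stopifnot(nrow(fixed) == n, length(plate) == n, length(date) == n)
  X <- buildDesign(fixed)
  eng <- crossedREMLEngine(X, plate, date)
  R <- matrix(0, nrow(M), n, dimnames = dimnames(M))
  s2 <- matrix(0, nrow(M), 3,
               dimnames = list(rownames(M), c("plate", "date", "residual")))
  for (j in seq_len(nrow(M))) {
    f <- eng$fit(M[j, ])
    R[j, ] <- f$residuals
    s2[j, ] <- f$sigma2
  }
  out <- MValueSet(R, cpgPositions(mset), stage = "technical",
                   colData = SummarizedExperiment::colData(mset))
  SummarizedExperiment::rowData(out) <- cbind(
    SummarizedExperiment::rowData(out), S4Vectors::DataFrame(s2))
  out
}

#' Stage-2 correction: familial and biological variation
#'
#' Fits, per CpG, a variance-component mixed model with the five
#' relationship matrices (G, K, F, C, S) as random-effect covariance
#' structures and sex, age and the six estimated blood cell proportions as
#' fixed effects, then returns whitened residuals
#' `sigma_e * V^{-1/2} (y - X beta)`. Whitening (rather than BLUP-removal,
#' whose residuals are anti-correlated between relatives because their
#' covariance is proportional to `V^{-1}`) leaves relatives' corrected
#' values uncorrelated under the fitted model and reduces to OLS residuals
#' when every matrix is the identity. Components supplied as identical
#' matrices (e.g. G = K in simulation) are collapsed into one before
#' fitting. CpGs whose REML fit does not converge fall back to
#' fixed-effects-only (OLS) residuals and are flagged in `rowData`.
#'
#' @param mset an [MValueSet-class] (typically stage `technical`).
#' @param rel a [RelationshipMatrixSet-class].
#' @param sex,age per-sample fixed covariates (defaults from `colData`).
#' @param cell_props matrix/data.frame of the six cell-proportion columns
#'   (CD8T, CD4T, NK, Bcell, Mono, Gran), defaults from `colData`.
#' @param tol,maxit REML controls (see [aiREML()]).
#' @return An [MValueSet-class] at stage `biological` with per-CpG variance
#'   components and a `reml_converged` flag in `rowData`.
#' @export
correctBiological <- function(mset, rel,
                              sex = SummarizedExperiment::colData(mset)$sex,
                              age = SummarizedExperiment::colData(mset)$age,
                              cell_props = as.matrix(as.data.frame(
                                SummarizedExperiment::colData(mset)[,
                                  c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")])),
                              tol = 1e-6, maxit = 50L) {
  M <- mValues(mset)
  n <- ncol(M)
  Klist <- relMatrices(rel)
  for (nm in names(Klist)) {
    if (nrow(Klist[[nm]]) != n) stop("relationship matrices are not aligned")
    if (!isPSD(Klist[[nm]])) stop("matrix ", nm, " is not positive semidefinite")
  }
  ## collapse components supplied as identical matrices (their shares are
  ## not separately identifiable); the share is reported under the first
  ## label and 0 under the duplicates
  labels <- names(Klist)
  rep_of <- labels
  for (a in seq_along(labels)) for (b in seq_len(a - 1L)) {
    if (rep_of[a] == labels[a] &&
        isTRUE(all.equal(Klist[[a]], Klist[[b]], tolerance = 1e-12,
                         check.attributes = FALSE)))
      rep_of[a] <- rep_of[b]
  }
  fitlabs <- unique(rep_of)
  ## a component equal to the identity is indistinguishable from residual
  ## noise; its share belongs to the residual by definition
  is_ident <- vapply(fitlabs, function(nm)
    isTRUE(all.equal(Klist[[nm]], diag(n), tolerance = 1e-12,
                     check.attributes = FALSE)), TRUE)
  fitlabs <- fitlabs[!is_ident]
  Kfit <- Klist[fitlabs]
  X <- buildDesign(data.frame(sex = sex, age = age, cell_props))
  R <- matrix(0, nrow(M), n, dimnames = dimnames(M))
  s2 <- matrix(0, nrow(M), 6,
               dimnames = list(rownames(M),
                               c("G", "K", "F", "C", "S", "residual")))
  ok <- logical(nrow(M))
  qrX <- qr(X)
  if (!length(Kfit)) {
    R <- t(qr.resid(qrX, t(M)))
    s2[, "residual"] <- rowSums(R^2) / (n - qrX$rank)
    out <- MValueSet(R, cpgPositions(mset), stage = "biological",
                     colData = SummarizedExperiment::colData(mset))
    SummarizedExperiment::rowData(out) <- cbind(
      SummarizedExperiment::rowData(out),
      S4Vectors::DataFrame(s2, reml_converged = rep(TRUE, nrow(M))))
    return(out)
  }
  for (j in seq_len(nrow(M))) {
    y <- M[j, ]
    fit <- tryCatch(aiREML(y, X, Kfit, tol = tol, maxit = maxit),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      V <- diag(rep(fit$sigma2[["residual"]], n))
      for (k in seq_along(Kfit)) V <- V + fit$sigma2[[k]] * Kfit[[k]]
      ev <- eigen(V, symmetric = TRUE)
      Vroot_inv <- ev$vectors %*% (t(ev$vectors) / sqrt(pmax(ev$values, 1e-12)))
      R[j, ] <- sqrt(fit$sigma2[["residual"]]) *
        drop(Vroot_inv %*% (y - X %*% fit$beta))
      s2[j, fitlabs] <- fit$sigma2[fitlabs]
      s2[j, "residual"] <- fit$sigma2[["residual"]]
      ok[j] <- TRUE
    } else {
      warning("REML did not converge for ", rownames(M)[j],
              "; using fixed-effects-only residuals", call. = FALSE)
      R[j, ] <- qr.resid(qrX, y)
      s2[j, ] <- NA_real_
    }
  }
  out <- MValueSet(R, cpgPositions(mset), stage = "biological",
                   colData = SummarizedExperiment::colData(mset))
  SummarizedExperiment::rowData(out) <- cbind(
    SummarizedExperiment::rowData(out),
    S4Vectors::DataFrame(s2, reml_converged = ok))
  out
}

# Build a full-rank fixed design with intercept from a covariate frame,
# erroring with the names of collinear columns.
buildDesign <- function(fixed) {
  fixed <- as.data.frame(fixed)
  for (j in seq_along(fixed))
    if (is.character(fixed[[j]])) fixed[[j]] <- factor(fixed[[j]])
  # constant columns (single-level factors, constant numerics) carry no
  # information beyond the intercept; drop them rather than erroring
  keep <- vapply(fixed, function(v) length(unique(v[!is.na(v)])) > 1L, TRUE)
  fixed <- fixed[, keep, drop = FALSE]
  if (!ncol(fixed))
    return(matrix(1, nrow(fixed), 1, dimnames = list(NULL, "(Intercept)")))
  X <- model.matrix(~ ., data = fixed)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[qr_X$pivot[-seq_len(qr_X$rank)]]
    stop("singular fixed design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}
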