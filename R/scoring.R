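#' Select discovery CpGs at a P-value threshold
#'
#' @param discovery_stats association table with `cpg_id`, `effect`, `p`.
#' @param p_threshold sites with `p` strictly below this are kept.
#' @return data.frame `cpg_id`, `effect` (possibly 0 rows).
#' @export
selectSites <- function(discovery_stats, p_threshold) {
  keep <- !is.na(discovery_stats$p) & discovery_stats$p < p_threshold
  discovery_stats[keep, c("cpg_id", "effect"), drop = FALSE]
}

#' Methylation profile score
#'
#' Per-sample weighted sum of M-values over the selected CpGs, weights
#' being the discovery effect sizes. Selected CpGs absent from the target
#' matrix are skipped (with a message); zero overlap is an error, as is any
#' sample shared between discovery and target (leakage guard).
#'
#' @param effects data.frame `cpg_id`, `effect` from [selectSites()] or an
#'   external weights file.
#' @param target an [MValueSet-class] or CpG-by-sample matrix.
#' @param discovery_samples optional character vector of discovery-set
#'   sample ids; any overlap with the target samples is an error.
#' @return list: `score` (named numeric per target sample), `n_cpgs` used,
#'   `n_skipped`.
#' @export
profileScore <- function(effects, target, discovery_samples = NULL) {
  M <- if (is(target, "MValueSet")) mValues(target) else as.matrix(target)
  if (!nrow(effects))
    stop("empty site selection: no CpGs passed the threshold, cannot score")
  if (!is.null(discovery_samples)) {
    shared <- intersect(discovery_samples, colnames(M))
    if (length(shared))
      stop("discovery and target sets share sample(s): ",
           paste(head(shared), collapse = ", "))
  }
  present <- effects$cpg_id %in% rownames(M)
  if (!any(present))
    stop("none of the selected CpGs are present in the target matrix")
  if (any(!present))
    message(sum(!present), " selected CpG(s) absent from target; skipped")
  eff <- effects[present, ]
  score <- drop(crossprod(M[eff$cpg_id, , drop = FALSE], eff$effect))
  list(score = setNames(score, colnames(M)), n_cpgs = nrow(eff),
       n_skipped = sum(!present))
}

# Nagelkerke R2 increment of `extra` over the null model log-likelihood.
nagelkerkeR2 <- function(ll0, ll1, n) {
  (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
}

#' Evaluate a profile score against a binary outcome
#'
#' Logistic regressions of the outcome on covariates alone and on
#' covariates + score; reports the Nagelkerke R2 increment attributable to
#' the score (covariate-only model as the reference likelihood) and the
#' likelihood-ratio P-value.
#'
#' @param score numeric per-sample score.
#' @param outcome 0/1 vector.
#' @param covariates data.frame (e.g. sex, age, principal components) or
#'   `NULL`.
#' @return list: `r2` (Nagelkerke), `p`, `n`, `df`.
#' @export
evaluateBinary <- function(score, outcome, covariates = NULL) {
  dat <- data.frame(outcome = outcome, score = score)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[complete.cases(dat), ]
  n <- nrow(dat)
  covterms <- setdiff(names(dat), c("outcome", "score"))
  f0 <- as.formula(paste("outcome ~",
                         if (length(covterms))
                           paste(covterms, collapse = " + ") else "1"))
  f1 <- stats::update.formula(f0, . ~ . + score)
  m0 <- glm(f0, family = binomial(), data = dat)
  m1 <- tryCatch(glm(f1, family = binomial(), data = dat),
                 warning = function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
      stop("perfect separation: the score separates cases and controls; ",
           "evaluate on more samples or drop collinear covariates")
    suppressWarnings(glm(f1, family = binomial(), data = dat))
  })
  ll0 <- as.numeric(logLik(m0)); ll1 <- as.numeric(logLik(m1))
  lr <- max(2 * (ll1 - ll0), 0)
  list(r2 = max(nagelkerkeR2(ll0, ll1, n), 0),
       p = pchisq(lr, df = 1, lower.tail = FALSE), n = n, df = 1)
}

#' Evaluate a profile score against a continuous outcome
#'
#' Linear regression; reports the adjusted-R2 increment of the score over
#' the covariate-only model and the partial F-test P-value.
#'
#' @inheritParams evaluateBinary
#' @param outcome numeric vector.
#' @return list: `r2` (adjusted increment, may be negative), `p`, `n`.
#' @export
evaluateContinuous <- function(score, outcome, covariates = NULL) {
  if (var(outcome, na.rm = TRUE) == 0) stop("outcome has zero variance")
  dat <- data.frame(outcome = outcome, score = score)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[complete.cases(dat), ]
  covterms <- setdiff(names(dat), c("outcome", "score"))
  f0 <- as.formula(paste("outcome ~",
                         if (length(covterms))
                           paste(covterms, collapse = " + ") else "1"))
  f1 <- stats::update.formula(f0, . ~ . + score)
  m0 <- lm(f0, data = dat); m1 <- lm(f1, data = dat)
  a <- anova(m0, m1)
  list(r2 = summary(m1)$adj.r.squared - summary(m0)$adj.r.squared,
       p = a[["Pr(>F)"]][2], n = nrow(dat))
}

#' Sweep profile-score thresholds and evaluate each
#'
#' Builds a score at every threshold, evaluates it against the outcome
#' (Nagelkerke R2 for binary outcomes, adjusted R2 for continuous), flags
#' the best-R2 threshold and judges significance against the
#' family-corrected gate `alpha_family / n_family` (default 0.05/8 =
#' 6.25e-3). Because the best threshold is selected after seeing the R2,
#' its P-value is optimistic; the per-threshold table is returned in full.
#'
#' @param discovery_stats association table (`cpg_id`, `effect`, `p`).
#' @param target target-set [MValueSet-class] or matrix.
#' @param outcome outcome vector aligned to target samples.
#' @param covariates data.frame or `NULL`.
#' @param thresholds P-value thresholds to sweep.
#' @param alpha_family,n_family family-wise gate parameters.
#' @param discovery_samples optional discovery sample ids (leakage guard).
#' @return data.frame: one row per threshold with `threshold`, `n_cpgs`,
#'   `r2`, `p`, `best` flag, `significant` (vs the gate), plus attribute
#'   `gate`.
#' @export
thresholdSweep <- function(discovery_stats, target, outcome,
                           covariates = NULL,
                           thresholds = 10^-(7:1),
                           alpha_family = 0.05, n_family = 8L,
                           discovery_samples = NULL) {
  stopifnot(length(thresholds) > 0)
  gate <- bonferroniThreshold(alpha_family, n_family)
  binary <- length(unique(na.omit(outcome))) == 2L
  rows <- lapply(sort(thresholds), function(thr) {
    sel <- selectSites(discovery_stats, thr)
    if (!nrow(sel))
      return(data.frame(threshold = thr, n_cpgs = 0L, r2 = NA_real_,
                        p = NA_real_))
    ps <- profileScore(sel, target, discovery_samples)
    ev <- if (binary) evaluateBinary(ps$score, outcome, covariates)
          else evaluateContinuous(ps$score, outcome, covariates)
    data.frame(threshold = thr, n_cpgs = ps$n_cpgs, r2 = ev$r2, p = ev$p)
  })
  out <- do.call(rbind, rows)
  out$best <- FALSE
  if (any(!is.na(out$r2)))
    out$best[which.max(out$r2)] <- TRUE
  out$significant <- !is.na(out$p) & out$p < gate
  attr(out, "gate") <- gate
  out
}
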