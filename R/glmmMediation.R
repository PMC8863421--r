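#' Kinship-aware regression of an outcome on an exposure
#'
#' Mixed model with a kinship-structured random effect: Gaussian outcomes
#' are fitted by REML (one variance ratio, profiled through the
#' eigendecomposition of the kinship matrix); binary outcomes by penalized
#' quasi-likelihood (logit link), re-estimating the kinship variance on the
#' working scale each iteration. Fixed effects are the exposure plus any
#' supplied covariates (sex by default in the intended use). Reported
#' P-values are Wald tests; judge the eight early-life exposures against
#' the family-wise gate 0.05/8.
#'
#' @param outcome numeric (continuous, or 0/1 for binomial).
#' @param exposure numeric or factor exposure of interest.
#' @param covariates data.frame of additional fixed effects (e.g. sex) or
#'   `NULL`.
#' @param kinship symmetric PSD kinship matrix aligned to samples.
#' @param family `"gaussian"`, `"binomial"` or `"auto"` (binomial iff the
#'   outcome takes two values).
#' @param max_iter PQL iteration limit.
#' @return list: `coef` (data.frame term/estimate/se/stat/p), `sigma2_g`,
#'   `sigma2_e` (Gaussian only), `family`, `converged`, `n`.
#' @export
glmmFit <- function(outcome, exposure, covariates = NULL, kinship,
                    family = c("auto", "gaussian", "binomial"),
                    max_iter = 25L) {
  family <- match.arg(family)
  dat <- data.frame(exposure = exposure)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  keep <- !is.na(outcome) & complete.cases(dat)
  y <- outcome[keep]
  X <- buildDesign(dat[keep, , drop = FALSE])
  K <- as.matrix(kinship)[keep, keep]
  if (!isPSD(K)) stop("kinship matrix is not positive semidefinite")
  n <- length(y)
  if (family == "auto")
    family <- if (length(unique(y)) == 2L) "binomial" else "gaussian"

  if (family == "gaussian") {
    e <- eigen(K, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    yt <- crossprod(e$vectors, y)
    Xt <- crossprod(e$vectors, X)
    p <- ncol(X)
    neg2 <- function(gam) {        # gam = sigma_g^2 / sigma_e^2
      w <- gam * lam + 1
      A <- crossprod(Xt / w, Xt)
      b <- crossprod(Xt / w, yt)
      cA <- chol(A)
      beta <- backsolve(cA, backsolve(cA, b, transpose = TRUE))
      rss <- sum(yt^2 / w) - sum(b * beta)
      s2e <- rss / (n - p)
      (n - p) * log(s2e) + sum(log(w)) + 2 * sum(log(diag(cA)))
    }
    opt <- optimize(function(lg) neg2(exp(lg)), c(-12, 8), tol = 1e-8)
    gam <- exp(opt$minimum)
    if (neg2(0) < opt$objective) gam <- 0
    w <- gam * lam + 1
    A <- crossprod(Xt / w, Xt)
    covb <- chol2inv(chol(A))
    beta <- drop(covb %*% crossprod(Xt / w, yt))
    s2e <- (sum(yt^2 / w) - sum(crossprod(Xt / w, yt) * beta)) / (n - p)
    se <- sqrt(diag(covb) * s2e)
    stat <- beta / se
    coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                        stat = stat, p = 2 * pnorm(-abs(stat)),
                        stringsAsFactors = FALSE)
    return(list(coef = coefs, sigma2_g = gam * s2e, sigma2_e = s2e,
                family = "gaussian", converged = TRUE, n = n))
  }

  ## binomial: PQL on the logit working scale
  beta <- qr.coef(qr(X), rep(qlogis(mean(pmin(pmax(y, 0.05), 0.95))), n))
  beta[is.na(beta)] <- 0
  g <- rep(0, n); s2g <- 0.2
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + g
    mu <- plogis(eta)
    Wv <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / Wv
    neg2 <- function(s2) {
      V <- s2 * K; diag(V) <- diag(V) + 1 / Wv
      cV <- chol(V)
      Vi <- chol2inv(cV)
      A <- crossprod(X, Vi %*% X)
      cA <- chol(A)
      b <- crossprod(X, Vi %*% z)
      bb <- backsolve(cA, backsolve(cA, b, transpose = TRUE))
      2 * sum(log(diag(cV))) + 2 * sum(log(diag(cA))) +
        sum(z * (Vi %*% z)) - sum(b * bb)
    }
    opt <- optimize(function(ls) neg2(exp(ls)), c(-10, 4), tol = 1e-4)
    s2g_new <- exp(opt$minimum)
    if (neg2(1e-8) < opt$objective) s2g_new <- 1e-8
    V <- s2g_new * K; diag(V) <- diag(V) + 1 / Wv
    Vi <- chol2inv(chol(V))
    covb <- chol2inv(chol(crossprod(X, Vi %*% X)))
    beta_new <- drop(covb %*% crossprod(X, Vi %*% z))
    r <- z - drop(X %*% beta_new)
    g_new <- drop(s2g_new * K %*% (Vi %*% r))
    delta <- max(abs(beta_new - beta), abs(s2g_new - s2g))
    beta <- beta_new; g <- g_new; s2g <- s2g_new
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  if (!converged)
    warning("PQL did not converge in ", max_iter, " iterations")
  se <- sqrt(diag(covb))
  stat <- beta / se
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      stat = stat,
                      p = if (converged) 2 * pnorm(-abs(stat)) else NA_real_,
                      stringsAsFactors = FALSE)
  list(coef = coefs, sigma2_g = s2g, sigma2_e = NA_real_,
       family = "binomial", converged = converged, n = n)
}

#' Mediation analysis by the product of coefficients
#'
#' Path `a` from the linear mediator model `mediator ~ exposure +
#' covariates`; paths `b` (mediator) and `c'` (direct) from the outcome
#' model `outcome ~ exposure + mediator + covariates` (logistic when the
#' outcome is binary, so `b`, `c'` and the indirect effect `a * b` are on
#' the log-odds linear-predictor scale). Percentile bootstrap confidence
#' intervals and two-sided P-values with a fixed seed. For a Gaussian
#' outcome the identity `total = direct + indirect` holds exactly on the
#' point estimates.
#'
#' @param exposure,mediator,outcome aligned vectors; the mediator must be
#'   continuous.
#' @param covariates data.frame or `NULL`.
#' @param n_boot bootstrap draws (>= 500).
#' @param seed RNG seed for resampling.
#' @return list: `estimates` (a, b, direct, indirect, total), `ci` (2.5/97.5
#'   percentile matrix), `p` (bootstrap two-sided), `family`, `n`, `n_boot`.
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    n_boot = 2000L, seed = 1L) {
  if (n_boot < 500L) stop("n_boot must be >= 500")
  dat <- data.frame(exposure = exposure, mediator = mediator,
                    outcome = outcome)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[complete.cases(dat), ]
  n <- nrow(dat)
  if (var(dat$mediator) == 0) stop("mediator is constant")
  binary <- length(unique(dat$outcome)) == 2L
  Xcov <- if (ncol(dat) > 3L)
    as.matrix(dat[, -(1:3), drop = FALSE]) else NULL

  paths <- function(d, Xc) {
    Xm <- cbind(1, d$exposure, Xc)
    a <- .lm.fit(Xm, d$mediator)$coefficients[2]
    Xy <- cbind(1, d$exposure, d$mediator, Xc)
    cf <- if (binary)
      suppressWarnings(glm.fit(Xy, d$outcome,
                               family = binomial())$coefficients)
    else .lm.fit(Xy, d$outcome)$coefficients
    c(a = unname(a), b = unname(cf[3]), direct = unname(cf[2]))
  }
  est <- paths(dat, Xcov)
  est <- c(est, indirect = unname(est["a"] * est["b"]),
           total = unname(est["direct"] + est["a"] * est["b"]))

  boots <- withStageSeed(seed, "mediation-bootstrap", {
    t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      pb <- tryCatch(paths(dat[i, ], if (is.null(Xcov)) NULL else
        Xcov[i, , drop = FALSE]), error = function(e)
          c(a = NA_real_, b = NA_real_, direct = NA_real_))
      c(pb, indirect = unname(pb["a"] * pb["b"]),
        total = unname(pb["direct"] + pb["a"] * pb["b"]))
    }, numeric(5)))
  })
  ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  pboot <- apply(boots, 2, function(v) {
    v <- v[!is.na(v)]
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  })
  list(estimates = est, ci = ci, p = pboot,
       family = if (binary) "binomial" else "gaussian",
       n = n, n_boot = n_boot, seed = seed)
}
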