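## Mixed-model machinery shared by the correction stages and the
## multi-component association engine.

# Profiled REML for y = X b + Z1 u1 + Z2 u2 + e with two crossed random
# intercepts, evaluated through the Woodbury identity so thousands of
# response vectors can share one set of design cross-products.
#
# Returns a closure environment; call $fit(y) per response.
crossedREMLEngine <- function(X, g1, g2) {
  n <- nrow(X)
  g1 <- as.integer(factor(g1)); g2 <- as.integer(factor(g2))
  q1 <- max(g1); q2 <- max(g2); q <- q1 + q2
  Z <- cbind(
    Matrix::sparseMatrix(i = seq_len(n), j = g1, x = 1, dims = c(n, q1)),
    Matrix::sparseMatrix(i = seq_len(n), j = g2, x = 1, dims = c(n, q2)))
  Z <- as.matrix(Z)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[qr_X$pivot[-seq_len(qr_X$rank)]]
    stop("singular fixed design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  pf <- ncol(X)
  XtX <- crossprod(X); ZtX <- crossprod(Z, X); ZtZ <- crossprod(Z)
  idx1 <- seq_len(q1); idx2 <- q1 + seq_len(q2)

  negtwoLR <- function(gam, Xty, Zty, yty) {
    d <- sqrt(c(rep(gam[1], q1), rep(gam[2], q2)))
    S <- ZtZ * tcrossprod(d); diag(S) <- diag(S) + 1
    cS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(cS)) return(list(obj = Inf))
    DZty <- d * Zty; DZtX <- d * ZtX
    u1 <- backsolve(cS, DZty, transpose = TRUE)
    U2 <- backsolve(cS, DZtX, transpose = TRUE)
    A <- XtX - crossprod(U2)              # sigma_e^2 * X' V^-1 X
    b <- Xty - crossprod(U2, u1)          # sigma_e^2 * X' V^-1 y
    cc <- yty - sum(u1^2)                 # sigma_e^2 * y' V^-1 y
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(list(obj = Inf))
    beta <- backsolve(cA, backsolve(cA, b, transpose = TRUE))
    rss <- max(cc - sum(b * beta), 1e-300)
    s2e <- rss / (n - pf)
    obj <- (n - pf) * log(s2e) + 2 * sum(log(diag(cS))) +
      2 * sum(log(diag(cA)))
    list(obj = obj, beta = beta, s2e = s2e, d = d, cS = cS)
  }

  fit <- function(y) {
    Xty <- crossprod(X, y); Zty <- crossprod(Z, y); yty <- sum(y^2)
    opt <- optim(c(0.1, 0.1),
                 function(g) negtwoLR(exp(g), Xty, Zty, yty)$obj,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 200))
    gam <- exp(opt$par)
    # allow the boundary (zero variance) to win if it fits better
    for (cand in list(c(0, 0), c(gam[1], 0), c(0, gam[2]))) {
      if (negtwoLR(pmax(cand, 0), Xty, Zty, yty)$obj < opt$value - 1e-8) {
        gam <- pmax(cand, 0)
        break
      }
    }
    fin <- negtwoLR(gam, Xty, Zty, yty)
    beta <- fin$beta
    # BLUP via the same Woodbury pieces, then Henderson residuals
    r0Z <- Zty - ZtX %*% beta             # Z'(y - X beta)
    d <- fin$d
    w <- d * backsolve(fin$cS, backsolve(fin$cS, d * r0Z, transpose = TRUE))
    gamvec <- c(rep(gam[1], q1), rep(gam[2], q2))
    u <- gamvec * (r0Z - ZtZ %*% w)
    resid <- y - X %*% beta - Z %*% u
    list(residuals = drop(resid), beta = drop(beta),
         sigma2 = c(group1 = gam[1] * fin$s2e, group2 = gam[2] * fin$s2e,
                    residual = fin$s2e))
  }
  list(fit = fit, n = n, q = c(q1, q2))
}

#' Average-information REML for dense variance components
#'
#' Fits `y = X b + sum_k g_k + e` with `g_k ~ N(0, sigma_k^2 K_k)` by
#' average-information REML, initialized by Haseman-Elston regression.
#' Negative component updates are clamped at a small floor and AI steps are
#' halved when they do not improve the restricted likelihood (EM-free,
#' boundary-tolerant).
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (include the intercept).
#' @param Klist named list of symmetric PSD covariance matrices.
#' @param tol convergence tolerance on the relative change of estimates.
#' @param maxit maximum iterations.
#' @param init optional starting values (length `length(Klist) + 1`,
#'   residual last).
#' @return list: `sigma2` (named, residual last), `beta`, `beta_se`,
#'   `beta_cov`, `Vinv`, `logLik` (-2 restricted), `converged`, `iterations`.
#' @export
aiREML <- function(y, X, Klist, tol = 1e-6, maxit = 50L, init = NULL) {
  n <- length(y)
  stopifnot(nrow(X) == n, all(vapply(Klist, nrow, 1L) == n))
  m <- length(Klist)
  vy <- var(y)
  floor_s <- 1e-8 * vy

  if (is.null(init)) init <- heInit(y, X, Klist)
  s <- pmax(init, floor_s)

  neg2 <- function(s) {
    V <- diag(rep(s[m + 1], n))
    for (k in seq_len(m)) V <- V + s[k] * Klist[[k]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vinv <- chol2inv(cV)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    cA <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    P <- Vinv - VinvX %*% chol2inv(cA) %*% t(VinvX)
    Py <- drop(P %*% y)
    obj <- 2 * sum(log(diag(cV))) + 2 * sum(log(diag(cA))) + sum(y * Py)
    list(obj = obj, P = P, Py = Py, Vinv = Vinv, XtVinvX = XtVinvX)
  }

  st <- neg2(s)
  if (is.null(st)) stop("variance-component model could not be initialized")
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    KPy <- vector("list", m + 1L)
    for (k in seq_len(m)) KPy[[k]] <- Klist[[k]] %*% st$Py
    KPy[[m + 1L]] <- st$Py
    score <- numeric(m + 1L)
    for (k in seq_len(m))
      score[k] <- -0.5 * (sum(st$P * Klist[[k]]) - sum(st$Py * KPy[[k]]))
    score[m + 1L] <- -0.5 * (sum(diag(st$P)) - sum(st$Py^2))
    AI <- matrix(0, m + 1L, m + 1L)
    PKPy <- lapply(KPy, function(v) st$P %*% v)
    for (k in seq_len(m + 1L)) for (l in k:(m + 1L))
      AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
    solveStep <- function(free) {
      delta <- rep(0, m + 1L)
      delta[free] <- tryCatch(
        solve(AI[free, free, drop = FALSE] + diag(1e-10, sum(free)),
              score[free]),
        error = function(e) score[free] / max(diag(AI)[free], 1))
      delta
    }
    free <- rep(TRUE, m + 1L)
    delta <- solveStep(free)
    # components pushed below the floor leave the AI system; re-solve for
    # the rest so boundary hits do not stall the remaining updates
    for (pass in seq_len(m)) {
      hit <- free & (s + delta < floor_s) & (abs(s - floor_s) < 2 * floor_s)
      if (!any(hit)) break
      free <- free & !hit
      if (!any(free)) break
      delta <- solveStep(free)
      delta[!free] <- floor_s - s[!free]
    }
    step <- 1
    stalled <- FALSE
    repeat {
      s_new <- pmax(s + step * delta, floor_s)
      st_new <- neg2(s_new)
      if (!is.null(st_new) && st_new$obj <= st$obj + 1e-8) break
      step <- step / 2
      if (step < 1e-4) { s_new <- s; st_new <- st; stalled <- TRUE; break }
    }
    rel <- max(abs(s_new - s)) / max(sum(s), 1e-12)
    obj_drop <- st$obj - st_new$obj
    s <- s_new; st <- st_new
    if ((rel < tol && !stalled) || (stalled && it > 1L) ||
        (it > 1L && obj_drop >= 0 && obj_drop < tol)) {
      converged <- TRUE
      break
    }
  }
  beta_cov <- chol2inv(chol(st$XtVinvX))
  beta <- drop(beta_cov %*% crossprod(X, st$Vinv %*% y))
  names(s) <- c(names(Klist), "residual")
  list(sigma2 = s, beta = beta, beta_se = sqrt(diag(beta_cov)),
       beta_cov = beta_cov, Vinv = st$Vinv, logLik = -0.5 * st$obj,
       converged = converged, iterations = it)
}

# Haseman-Elston initialization: least-squares fit of the OLS-residual
# cross-products to the covariance structures.
heInit <- function(y, X, Klist) {
  m <- length(Klist)
  r <- qr.resid(qr(X), y)
  RR <- tcrossprod(r)
  mats <- c(Klist, list(diag(length(y))))
  Smat <- matrix(0, m + 1L, m + 1L)
  rhs <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    rhs[k] <- sum(mats[[k]] * RR)
    for (l in k:(m + 1L))
      Smat[k, l] <- Smat[l, k] <- sum(mats[[k]] * mats[[l]])
  }
  est <- tryCatch(solve(Smat, rhs), error = function(e)
    rep(var(y) / (m + 1), m + 1L))
  pmax(est, 0.01 * var(y) / (m + 1))
}
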