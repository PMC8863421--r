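#' @importFrom methods new validObject is slotNames callNextMethod
#' @importFrom stats coef lm lm.fit glm binomial quantile median var sd cor
#'   rnorm runif rbinom qnorm pnorm pt qt pchisq qchisq pf phyper dhyper
#'   integrate optim optimize prcomp complete.cases model.matrix resid
#'   p.adjust setNames anova logLik as.formula qbeta na.omit fitted rgamma
#'   plogis qlogis glm.fit .lm.fit predict ave
#' @importFrom utils head tail modifyList packageVersion
#' @importFrom tools md5sum
NULL

# Derive a reproducible sub-seed for a named pipeline stage from one global
# integer seed.  Keeps every derived seed in [1, 2^31 - 2] (R integer range).
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v))
  as.integer(1 + (abs(seed) * 7919 + h * 104729) %% 2147483645)
}

# Run expr under a stage-derived seed without disturbing the caller's RNG.
withStageSeed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stageSeed(seed, stage))
  expr
}

# Symmetric PSD check with a tolerance scaled to the largest eigenvalue.
isPSD <- function(A, tol = 1e-8) {
  if (!isSymmetric(unname(A), tol = 1e-8)) return(FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev[1] <= 0 || min(ev) > -tol * max(abs(ev))
}

# Factor a PSD matrix for correlated draws: A ~ L %*% t(L), clamping tiny
# negative eigenvalues that arise from round-off.
psdFactor <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(d), nrow = length(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standardize a vector to mean 0, sample-SD 1 over non-missing entries.
zscore <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values to standardize")
  s <- sd(x[ok])
  if (s == 0) stop("zero variance: cannot standardize a constant vector")
  (x - mean(x[ok])) / s
}
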