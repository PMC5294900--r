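# Internal matrix-level fitting engines. The exported wrappers in fit.R build
# design matrices from data frames and back-transform standardized
# coefficients; the engines are also called directly from the simulation hot
# loop in run_scenario(), where formula handling would dominate runtime.

glm_ctrl <- function() stats::glm.control(epsilon = 1e-8, maxit = 100)

# numerically stable log(1 + exp(eta))
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

# unscaled covariance of a glm.fit result: (X'WX)^{-1} with IRLS weights
unscaled_cov <- function(X, w) {
  info <- crossprod(X, X * w)
  tryCatch(solve(info), error = function(e) NULL)
}

# Negative binomial (or Poisson when phi == 0) log-link GLM at fixed
# dispersion. The Wald covariance is scaled by the Pearson dispersion
# estimate for NB fits, matching summary.glm() on a negative.binomial family
# (the construction used by the study this package reproduces); Poisson fits
# use scale 1.
nb_engine <- function(y, X, phi, offset = NULL) {
  if (all(y == 0)) {
    abort("degenerate gene: all counts are zero", class = "firthde_degenerate_gene")
  }
  fam <- if (phi < 1e-12) poisson() else MASS::negative.binomial(theta = 1 / phi)
  p <- ncol(X)
  fail <- list(coef = rep(NA_real_, p), se = rep(NA_real_, p), stat = NA_real_,
               pvalue = NA_real_, converged = FALSE, n_iter = 0L)
  fit <- tryCatch(
    suppressWarnings(glm.fit(x = X, y = y, family = fam, offset = offset,
                             control = glm_ctrl())),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)   # IRLS diverged
  bad <- anyNA(fit$coefficients) || fit$rank < p
  cov <- if (!bad) unscaled_cov(X, fit$weights) else NULL
  if (bad || is.null(cov)) {
    return(list(coef = rep(NA_real_, p), se = rep(NA_real_, p), stat = NA_real_,
                pvalue = NA_real_, converged = FALSE, n_iter = fit$iter))
  }
  df_r <- fit$df.residual
  scale <- if (phi < 1e-12 || df_r <= 0) 1 else
    sum((fit$weights * fit$residuals^2)[fit$weights > 0]) / df_r
  se <- sqrt(pmax(diag(cov) * scale, 0))
  z <- fit$coefficients[2L] / se[2L]
  list(coef = fit$coefficients, se = se, stat = z,
       pvalue = if (fit$converged) 2 * pnorm(-abs(z)) else NA_real_,
       converged = fit$converged, n_iter = fit$iter)
}

# Classical (maximum likelihood) logistic regression. Expects the primary
# predictor in column 2, already standardized by the caller so the
# separation thresholds below are scale-free.
cl_engine <- function(y, X, sep_coef = 15, sep_prob = 1e-10) {
  p <- ncol(X)
  fail <- list(coef = rep(NA_real_, p), se = rep(NA_real_, p), stat = NA_real_,
               pvalue = NA_real_, converged = FALSE, n_iter = 0L)
  fit <- tryCatch(
    suppressWarnings(glm.fit(x = X, y = y, family = binomial(),
                             control = glm_ctrl())),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  if (anyNA(fit$coefficients) || fit$rank < p) {
    fail$n_iter <- fit$iter
    return(fail)
  }
  mu <- fit$fitted.values
  separated <- abs(fit$coefficients[2L]) > sep_coef ||
    any(mu < sep_prob | mu > 1 - sep_prob)
  converged <- fit$converged && !separated
  cov <- unscaled_cov(X, fit$weights)
  if (is.null(cov)) converged <- FALSE
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else rep(NA_real_, p)
  z <- fit$coefficients[2L] / se[2L]
  list(coef = fit$coefficients, se = se, stat = z,
       pvalue = if (converged) 2 * pnorm(-abs(z)) else NA_real_,
       converged = converged, n_iter = fit$iter)
}

# Bayes logistic regression: posterior mode under independent Cauchy priors
# (Gelman et al.), computed by an EM step for the prior scale embedded in
# IRLS. Predictors are standardized internally (binary columns centered,
# others centered and scaled to sd 0.5); estimates are reported on the
# original scale.
bl_engine <- function(y, X, prior_scale = 2.5, prior_df = 1,
                      intercept_scale = 10, intercept_df = 1,
                      maxit = 200, tol = 1e-8) {
  p <- ncol(X)
  centers <- rep(0, p)
  scales <- rep(1, p)
  Xs <- X
  for (j in seq_len(p)[-1L]) {
    xj <- X[, j]
    u <- unique(xj)
    centers[j] <- mean(xj)
    if (length(u) > 2L) {
      s <- sd(xj)
      if (s > 0) scales[j] <- 2 * s
    }
    Xs[, j] <- (xj - centers[j]) / scales[j]
  }
  s0 <- c(intercept_scale, rep(prior_scale, p - 1L))
  df0 <- c(intercept_df, rep(prior_df, p - 1L))
  beta <- rep(0, p)
  converged <- FALSE
  it <- 0L
  cov <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(Xs %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sigma2 <- (df0 * s0^2 + beta^2) / (df0 + 1)
    A <- crossprod(Xs, Xs * w) + diag(1 / sigma2, p)
    bnew <- tryCatch(solve(A, crossprod(Xs, w * z)), error = function(e) NULL)
    if (is.null(bnew)) break
    bnew <- drop(bnew)
    delta <- max(abs(bnew - beta))
    beta <- bnew
    if (delta < tol) {
      converged <- TRUE
      cov <- tryCatch(solve(A), error = function(e) NULL)
      break
    }
  }
  if (is.null(cov)) converged <- FALSE
  se_s <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else rep(NA_real_, p)
  coef <- beta / scales
  coef[1L] <- beta[1L] - sum((beta[-1L] * centers[-1L] / scales[-1L]))
  se <- se_s / scales
  z <- coef[2L] / se[2L]
  list(coef = coef, se = se, stat = z,
       pvalue = if (converged) 2 * pnorm(-abs(z)) else NA_real_,
       converged = converged, n_iter = it)
}

fl_penll <- function(y, X, beta) {
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  info <- crossprod(X, X * pmax(mu * (1 - mu), 0))
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  sum(y * eta - log1pexp(eta)) + 0.5 * as.numeric(ld$modulus)
}

# One Firth-penalized Newton solve with step halving; `fixed` constrains a
# coefficient (used for the penalized likelihood-ratio test, where the Firth
# penalty is evaluated on the full-model information at the constrained
# coefficients).
fl_solve <- function(y, X, fixed_idx = integer(), fixed_val = numeric(),
                     maxit = 200, tol = 1e-6) {
  p <- ncol(X)
  beta <- rep(0, p)
  beta[fixed_idx] <- fixed_val
  free <- setdiff(seq_len(p), fixed_idx)
  converged <- FALSE
  it <- 0L
  info <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 0)
    XW <- X * w
    info <- crossprod(X, XW)
    iinv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(iinv)) return(NULL)
    h <- rowSums((X %*% iinv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (max(abs(score[free])) < tol) {
      converged <- TRUE
      break
    }
    step <- rep(0, p)
    step[free] <- tryCatch(solve(info[free, free, drop = FALSE], score[free]),
                           error = function(e) NULL)
    if (anyNA(step)) return(NULL)
    ll0 <- fl_penll(y, X, beta)
    lambda <- 1
    for (k in 1:15) {
      cand <- beta + lambda * step
      if (fl_penll(y, X, cand) >= ll0 - 1e-12) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
  }
  list(beta = beta, penll = fl_penll(y, X, beta), info = info,
       converged = converged, n_iter = it)
}

# Firth's penalized-likelihood logistic regression for the predictor in
# column 2: finite estimates under complete separation, default p-value from
# the penalized likelihood-ratio test, Wald optional.
fl_engine <- function(y, X, test = c("plr", "wald"), maxit = 200, tol = 1e-6) {
  test <- match.arg(test)
  p <- ncol(X)
  full <- fl_solve(y, X, maxit = maxit, tol = tol)
  fail <- list(coef = rep(NA_real_, p), se = rep(NA_real_, p), stat = NA_real_,
               pvalue = NA_real_, converged = FALSE, n_iter = maxit)
  if (is.null(full)) return(fail)
  cov <- tryCatch(solve(full$info), error = function(e) NULL)
  if (is.null(cov)) return(fail)
  se <- sqrt(pmax(diag(cov), 0))
  converged <- full$converged
  if (test == "plr") {
    red <- fl_solve(y, X, fixed_idx = 2L, fixed_val = 0, maxit = maxit, tol = tol)
    if (is.null(red)) return(fail)
    converged <- converged && red$converged
    stat <- max(2 * (full$penll - red$penll), 0)
    pval <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- full$beta[2L] / se[2L]
    pval <- 2 * pnorm(-abs(stat))
  }
  list(coef = full$beta, se = se, stat = stat,
       pvalue = if (converged) pval else NA_real_,
       converged = converged, n_iter = full$n_iter)
}
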