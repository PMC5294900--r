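# Independent brute-force oracles used to check the fitters against their
# own objectives. Everything here is written from the model definitions,
# not from the package internals.

# log-likelihood of a logistic regression
oracle_logit_ll <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# Firth-penalized logistic log-likelihood
oracle_firth_ll <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * (p * (1 - p)))
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  oracle_logit_ll(beta, y, X) + 0.5 * as.numeric(ld$modulus)
}

# log posterior of the Cauchy-prior logistic model on the standardized scale
oracle_bayes_ll <- function(beta, y, Xs, scales = c(10, rep(2.5, ncol(Xs) - 1))) {
  oracle_logit_ll(beta, y, Xs) + sum(stats::dcauchy(beta, 0, scales, log = TRUE))
}

# maximize an objective by multi-start Nelder-Mead refined with BFGS
oracle_maximize <- function(obj, p, starts = list(rep(0, p))) {
  best <- NULL
  for (s in starts) {
    o1 <- stats::optim(s, obj, control = list(fnscale = -1, maxit = 5000))
    o2 <- stats::optim(o1$par, obj, method = "BFGS",
                       control = list(fnscale = -1, maxit = 1000, reltol = 1e-14))
    if (is.null(best) || o2$value > best$value) best <- o2
  }
  best$par
}

# NB profile log-likelihood for a two-group design: the fitted means are the
# group means for any dispersion, so the profile is closed-form in phi
oracle_nb_profile <- function(y, status, phi) {
  mu <- ifelse(status == 1, mean(y[status == 1]), mean(y[status == 0]))
  if (phi < 1e-12) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

oracle_ml_dispersion_grid <- function(y, status, grid = seq(0, 10, by = 1e-4)) {
  ll <- vapply(grid, function(phi) oracle_nb_profile(y, status, phi), numeric(1))
  grid[which.max(ll)]
}

# Pearson moment condition for the QL dispersion, solved by plain bisection
oracle_ql_dispersion_bisect <- function(y, status, upper = 1e3, iters = 60) {
  gap <- function(phi) {
    mu <- ifelse(status == 1, mean(y[status == 1]), mean(y[status == 0]))
    sum((y - mu)^2 / (mu + phi * mu^2)) - (length(y) - 2)
  }
  if (gap(0) <= 0) return(0)
  lo <- 0; hi <- upper
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Benjamini-Hochberg step-up worked by its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# small deterministic logistic datasets without separation
toy_logistic_sets <- function() {
  list(
    list(y = c(0, 1, 0, 1, 1, 0, 0, 1),
         x = c(0.2, 0.8, 1.1, -0.3, 0.9, 1.4, -0.7, 0.5)),
    list(y = c(1, 0, 0, 1, 1, 0, 1, 0),
         x = c(1.5, 0.6, -0.2, 0.1, 0.9, 1.1, -0.8, 0.4)),
    list(y = c(0, 1, 0, 1, 0, 1),
         x = c(-0.5, 0.2, 0.4, 1.3, 0.9, -0.1)))
}
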