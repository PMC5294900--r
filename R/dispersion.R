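#' Estimate the negative binomial dispersion of one gene
#'
#' Two estimators of the per-gene dispersion \eqn{\phi} (variance
#' \eqn{\mu + \phi\mu^2}) from a single gene's counts and design:
#' \describe{
#'   \item{ML}{profile maximum likelihood: for each candidate \eqn{\phi} the
#'     mean model is refit and the NB log-likelihood evaluated; the profile
#'     is maximized by bounded scalar optimization on \eqn{\log\phi} over
#'     \[1e-8, 1e3\], with the Poisson boundary \eqn{\phi = 0} compared
#'     explicitly.}
#'   \item{QL}{quasi-likelihood / moment estimator: \eqn{\phi} solves
#'     \eqn{\sum_i (y_i - \hat\mu_i)^2 / (\hat\mu_i + \phi\hat\mu_i^2) = n - p}
#'     (Pearson chi-square equals residual degrees of freedom), found by
#'     bisection; the mean model is refit at each \eqn{\phi}.}
#' }
#' Underdispersed data (Pearson ratio below 1 at \eqn{\phi = 0}) yield
#' \eqn{\hat\phi = 0} with `converged = TRUE`.
#'
#' @inheritParams fit_nb_glm
#' @param method `"ML"` or `"QL"`.
#' @return An object of class `fde_dispersion` with fields `phi`, `method`,
#'   `converged`.
#' @examples
#' d <- data.frame(counts = rnbinom(200, mu = 100, size = 2),
#'                 status = rep(0:1, each = 100))
#' estimate_dispersion(d, method = "ML")$phi
#' @export
estimate_dispersion <- function(data, counts = "counts", status = "status",
                                covariates = NULL, method = c("ML", "QL")) {
  method <- match.arg(method)
  y <- check_counts(data[[counts]])
  d <- check_status(data[[status]])
  if (min(sum(d == 0), sum(d == 1)) < 3L) {
    abort("at least 3 samples per group are required to estimate dispersion")
  }
  X <- design_matrix(d, data, covariates)
  est <- if (method == "ML") disp_ml(y, X) else disp_ql(y, X)
  new_fde_dispersion(est$phi, method, est$converged)
}

new_fde_dispersion <- function(phi, method, converged = TRUE) {
  structure(list(phi = phi, method = method, converged = converged),
            class = "fde_dispersion")
}

#' @export
print.fde_dispersion <- function(x, ...) {
  cat(sprintf("<fde_dispersion> phi = %.6g (%s%s)\n", x$phi, x$method,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @rdname estimate_dispersion
#' @param x An `fde_dispersion` object.
#' @param ... Unused.
#' @export
tidy.fde_dispersion <- function(x, ...) {
  tibble(phi = x$phi, method = x$method, converged = x$converged)
}

nb_fitted_means <- function(y, X, phi, offset = NULL) {
  fam <- if (phi < 1e-12) poisson() else MASS::negative.binomial(theta = 1 / phi)
  fit <- suppressWarnings(glm.fit(x = X, y = y, family = fam, offset = offset,
                                  control = glm_ctrl()))
  fit$fitted.values
}

nb_profile_ll <- function(y, X, phi, offset = NULL) {
  mu <- nb_fitted_means(y, X, phi, offset)
  if (phi < 1e-12) sum(stats::dpois(y, lambda = mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

pearson_gap <- function(y, X, phi, offset = NULL) {
  mu <- nb_fitted_means(y, X, phi, offset)
  sum((y - mu)^2 / (mu + phi * mu^2)) - (length(y) - ncol(X))
}

disp_ml <- function(y, X, lower = 1e-8, upper = 1e3, offset = NULL) {
  opt <- tryCatch(
    optimize(function(lp) nb_profile_ll(y, X, exp(lp), offset),
             interval = log(c(lower, upper)), maximum = TRUE, tol = 1e-10),
    error = function(e) NULL)
  if (is.null(opt)) return(list(phi = NA_real_, converged = FALSE))
  phi <- exp(opt$maximum)
  ll0 <- nb_profile_ll(y, X, 0, offset)
  if (ll0 >= opt$objective || phi <= lower * 2) {
    return(list(phi = 0, converged = TRUE))
  }
  list(phi = phi, converged = TRUE)
}

disp_ql <- function(y, X, upper = 1e3, offset = NULL) {
  g0 <- pearson_gap(y, X, 0, offset)
  if (g0 <= 0) return(list(phi = 0, converged = TRUE))   # at or below Poisson
  if (pearson_gap(y, X, upper, offset) > 0) {
    return(list(phi = upper, converged = FALSE))
  }
  root <- tryCatch(
    uniroot(function(phi) pearson_gap(y, X, phi, offset), lower = 0,
            upper = upper, tol = 1e-9),
    error = function(e) NULL)
  if (is.null(root)) return(list(phi = NA_real_, converged = FALSE))
  list(phi = max(root$root, 0), converged = TRUE)
}
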