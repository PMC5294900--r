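#' @title Regression fitters for case-control differential expression
#' @description
#' Two modelling directions are available for a single gene:
#' \describe{
#'   \item{Model A (counts as outcome)}{[fit_nb_glm()]: negative binomial
#'     GLM \eqn{\log E[Y] = \beta_0 + \beta_1 D + \sum_k \beta_{k+1} X_k}
#'     with variance \eqn{\mu + \phi\mu^2} at fixed dispersion \eqn{\phi}.}
#'   \item{Model B (status as outcome)}{[fit_classical_logistic()],
#'     [fit_bayes_logistic()] and [fit_firth_logistic()]:
#'     \eqn{\mathrm{logit}\, E[D] = \beta_0^* + \beta_1^* Y + \sum_k
#'     \beta_{k+1}^* X_k}.}
#' }
#' All fitters take a data frame with one row per sample and return an object
#' of class `fde_fit`; [tidy()] turns it into a one-row tibble. The reported
#' `coef` is the association coefficient (\eqn{\beta_1} or \eqn{\beta_1^*})
#' on the natural-log scale, per unit of the original predictor.
#' Non-converged fits carry `pvalue = NA`.
#' @name fitters
NULL

new_fde_fit <- function(method, eng, idx = 2L, stat_type = "z",
                        dispersion_used = NA_real_, n = NA_integer_,
                        n_cases = NA_integer_, scale = 1, center = 0) {
  coef <- eng$coef[idx] / scale
  se <- eng$se[idx] / scale
  structure(
    list(method = method,
         coef = unname(coef),
         se = unname(se),
         stat = unname(eng$stat),
         stat_type = stat_type,
         pvalue = unname(eng$pvalue),
         converged = eng$converged,
         n_iter = eng$n_iter,
         dispersion_used = dispersion_used,
         n = n, n_cases = n_cases),
    class = "fde_fit")
}

#' @export
print.fde_fit <- function(x, ...) {
  cat(sprintf("<fde_fit> %s: coef = %.4g, se = %.4g, %s = %.4g, p = %.4g (%s)\n",
              x$method, x$coef, x$se, x$stat_type, x$stat, x$pvalue,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname fitters
#' @param x An `fde_fit` object.
#' @param ... Unused.
#' @export
tidy.fde_fit <- function(x, ...) {
  tibble(method = x$method, coef = x$coef, se = x$se, stat = x$stat,
         stat_type = x$stat_type, pvalue = x$pvalue, converged = x$converged,
         n_iter = x$n_iter, dispersion_used = x$dispersion_used)
}

#' @rdname fitters
#' @export
glance.fde_fit <- function(x, ...) {
  tibble(method = x$method, n = x$n, n_cases = x$n_cases,
         converged = x$converged, n_iter = x$n_iter)
}

check_status <- function(status) {
  if (anyNA(status)) abort("status contains missing values")
  if (!all(status %in% c(0, 1))) abort("status must be coded 0 (control) / 1 (case)")
  if (length(unique(status)) < 2L) abort("both cases and controls must be present")
  as.numeric(status)
}

check_counts <- function(y) {
  if (anyNA(y)) abort("counts contain missing values")
  if (any(y < 0) || any(y != round(y))) abort("counts must be non-negative integers")
  as.numeric(y)
}

pull_cols <- function(data, cols) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found in data: ", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("covariate columns contain missing values")
  m
}

design_matrix <- function(primary, data, covariates) {
  X <- cbind(1, primary)
  if (length(covariates)) X <- cbind(X, pull_cols(data, covariates))
  X
}

#' Negative binomial regression of counts on disease status (Model A)
#'
#' Fits a log-link negative binomial GLM of read counts on case-control
#' status (plus optional covariates) at a fixed dispersion \eqn{\phi}, with
#' variance \eqn{\mu + \phi\mu^2}. The two-sided Wald p-value uses the
#' Pearson-scaled covariance, matching an R `glm()` fit with a
#' `MASS::negative.binomial` family. `dispersion` may be a number (e.g. the
#' known simulation value), an [estimate_dispersion()] result, or `"ML"` /
#' `"QL"` to estimate it from the same data first.
#'
#' @param data Data frame, one row per sample.
#' @param counts,status Names of the count and 0/1 status columns.
#' @param covariates Character vector of covariate column names (optional).
#' @param dispersion Dispersion \eqn{\phi \ge 0}, an `fde_dispersion`
#'   object, or `"ML"` / `"QL"`.
#' @param offset Optional per-sample log size-factor offset.
#' @return An `fde_fit` object.
#' @examples
#' d <- data.frame(counts = rnbinom(40, mu = 100, size = 10),
#'                 status = rep(0:1, each = 20))
#' tidy(fit_nb_glm(d, dispersion = 0.1))
#' @export
fit_nb_glm <- function(data, counts = "counts", status = "status",
                       covariates = NULL, dispersion, offset = NULL) {
  y <- check_counts(data[[counts]])
  d <- check_status(data[[status]])
  if (inherits(dispersion, "fde_dispersion")) {
    phi <- dispersion$phi
    disp_method <- dispersion$method
  } else if (is.character(dispersion)) {
    est <- estimate_dispersion(data, counts = counts, status = status,
                               covariates = covariates,
                               method = toupper(dispersion))
    phi <- est$phi
    disp_method <- est$method
  } else {
    phi <- as.numeric(dispersion)
    disp_method <- "TRUE"
  }
  if (is.na(phi) || phi < 0) abort("dispersion must be >= 0")
  X <- design_matrix(d, data, covariates)
  eng <- nb_engine(y, X, phi, offset = offset)
  new_fde_fit("NB", eng, dispersion_used = phi,
              n = length(y), n_cases = sum(d == 1))
}

# shared front end for the three Model B fitters: standardizes the expression
# predictor for numerical stability and back-transforms coef/se to per-count
model_b_fit <- function(data, expression, status, covariates, engine, method,
                        stat_type = "z", ...) {
  x <- as.numeric(data[[expression]])
  if (anyNA(x)) abort("expression contains missing values")
  d <- check_status(data[[status]])
  s <- sd(x)
  if (s == 0) {
    # constant predictor carries no information: null fit by convention
    return(structure(
      list(method = method, coef = 0, se = Inf, stat = 0, stat_type = stat_type,
           pvalue = 1, converged = TRUE, n_iter = 0L,
           dispersion_used = NA_real_, n = length(d), n_cases = sum(d == 1)),
      class = "fde_fit"))
  }
  xs <- (x - mean(x)) / s
  X <- design_matrix(xs, data, covariates)
  eng <- engine(d, X, ...)
  new_fde_fit(method, eng, stat_type = stat_type, scale = s,
              n = length(d), n_cases = sum(d == 1))
}

#' Classical logistic regression of status on expression (Model B)
#'
#' Maximum-likelihood logistic fit with a two-sided Wald test. Complete or
#' quasi-complete separation of cases and controls by the expression values
#' makes the MLE infinite; such fits are flagged `converged = FALSE`
#' (detected as |standardized coef| > 15 or fitted probabilities within
#' 1e-10 of 0/1) and carry no p-value, so they drop out of downstream
#' Type-I-error / power denominators.
#'
#' @inheritParams fit_nb_glm
#' @param expression Name of the expression (count) predictor column.
#' @return An `fde_fit` object.
#' @export
fit_classical_logistic <- function(data, expression = "counts",
                                   status = "status", covariates = NULL) {
  model_b_fit(data, expression, status, covariates, cl_engine, "CL")
}

#' Bayes logistic regression with Cauchy priors (Model B)
#'
#' Posterior-mode logistic fit under independent Cauchy(0, 2.5) priors on
#' standardized coefficients and Cauchy(0, 10) on the intercept (Gelman et
#' al.'s weakly informative default), computed by an EM step embedded in
#' IRLS. Estimates stay finite under complete separation. Binary predictors
#' are centered; others are centered and scaled to sd 0.5; results are
#' reported on the original scale.
#'
#' @inheritParams fit_classical_logistic
#' @param prior_scale Cauchy prior scale for standardized coefficients.
#' @return An `fde_fit` object.
#' @export
fit_bayes_logistic <- function(data, expression = "counts", status = "status",
                               covariates = NULL, prior_scale = 2.5) {
  model_b_fit(data, expression, status, covariates, bl_engine, "BL",
              prior_scale = prior_scale)
}

#' Firth's penalized logistic regression (Model B)
#'
#' Maximizes the Firth-penalized log-likelihood
#' \eqn{\ell(\beta) + \tfrac12 \log\det I(\beta)}, which removes the
#' first-order bias of the MLE and guarantees finite estimates under
#' complete separation. The default p-value is the penalized
#' likelihood-ratio test for the expression coefficient; `test = "wald"`
#' uses the penalized-information Wald test instead.
#'
#' @inheritParams fit_classical_logistic
#' @param test `"plr"` (default) or `"wald"`.
#' @return An `fde_fit` object.
#' @examples
#' # complete separation: CL diverges, FL returns the 1/2-cell-corrected
#' # log odds ratio log((5.5 * 5.5) / (0.5 * 0.5)) = 4.7958
#' d <- data.frame(counts = rep(c(1, 0), each = 5), status = rep(c(1, 0), each = 5))
#' fit_firth_logistic(d)$coef
#' @export
fit_firth_logistic <- function(data, expression = "counts", status = "status",
                               covariates = NULL, test = c("plr", "wald")) {
  test <- match.arg(test)
  model_b_fit(data, expression, status, covariates, fl_engine, "FL",
              stat_type = if (test == "plr") "chisq" else "z", test = test)
}

#' Fit several methods to one gene
#'
#' Convenience wrapper running any subset of NB, CL, BL, FL on the same
#' samples and row-binding the tidied results.
#'
#' @inheritParams fit_nb_glm
#' @param methods Subset of `c("NB", "CL", "BL", "FL")`.
#' @param dispersion Dispersion for the NB fit (number, estimate object, or
#'   `"ML"` / `"QL"`).
#' @return A tibble with one row per method.
#' @export
fit_gene <- function(data, methods = c("NB", "CL", "BL", "FL"),
                     counts = "counts", status = "status", covariates = NULL,
                     dispersion = "ML") {
  methods <- match.arg(methods, c("NB", "CL", "BL", "FL"), several.ok = TRUE)
  fits <- lapply(methods, function(m) {
    f <- switch(m,
      NB = fit_nb_glm(data, counts, status, covariates, dispersion = dispersion),
      CL = fit_classical_logistic(data, counts, status, covariates),
      BL = fit_bayes_logistic(data, counts, status, covariates),
      FL = fit_firth_logistic(data, counts, status, covariates))
    tidy(f)
  })
  dplyr::bind_rows(fits)
}

#' Two-sided Wald p-value
#'
#' \eqn{p = 2(1 - \Phi(|\hat\beta / \mathrm{se}|))}. Vectorized.
#'
#' @param coef Coefficient estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return p-value(s) in \[0, 1\].
#' @export
wald_pvalue <- function(coef, se) {
  if (any(se <= 0 | is.na(se))) abort("se must be > 0")
  2 * pnorm(-abs(coef / se))
}
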