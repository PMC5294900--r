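# Scenario evaluation: Type-I error, empirical thresholds, empirical power,
# bias, convergence tracking.

wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(center - half, 0), high = min(center + half, 1))
}

#' Type-I error rate from null-scenario p-values
#'
#' Proportion of converged replicates with `p < alpha`; non-converged
#' replicates are removed from both numerator and denominator. A Wilson 95%
#' confidence interval is attached.
#'
#' @param pvalues Vector of p-values (may contain NA for non-converged fits).
#' @param converged Logical vector; defaults to `!is.na(pvalues)`.
#' @param alpha Nominal level in (0, 1).
#' @return One-row tibble: `alpha`, `rate`, `ci_low`, `ci_high`,
#'   `n_converged`, `n_total`.
#' @export
type1_error <- function(pvalues, converged = NULL, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (is.null(converged)) converged <- !is.na(pvalues)
  p <- pvalues[converged & !is.na(pvalues)]
  if (!length(p)) abort("no converged replicates; Type-I error undefined")
  k <- sum(p < alpha)
  ci <- wilson_ci(k, length(p))
  tibble(alpha = alpha, rate = k / length(p), ci_low = ci[["low"]],
         ci_high = ci[["high"]], n_converged = length(p),
         n_total = length(pvalues))
}

#' Empirical p-value threshold from a null scenario
#'
#' The floor(alpha * M)-th smallest of M converged null p-values. Rejection
#' downstream is strict (`p < threshold`), so re-applying the threshold to
#' its own null set rejects at a rate no greater than `alpha` (equality up
#' to 1/M). Methods with conservative null p-values get thresholds above
#' `alpha`, liberal methods below, making power comparisons
#' calibration-fair.
#'
#' @param null_pvalues Converged null-scenario p-values.
#' @param alpha Nominal level; at least `1/alpha` values are required.
#' @return Scalar threshold.
#' @export
empirical_threshold <- function(null_pvalues, alpha = 0.05) {
  p <- null_pvalues[!is.na(null_pvalues)]
  k <- floor(alpha * length(p))
  if (k < 1) abort("too few null p-values for this alpha (need at least 1/alpha)")
  sort(p, partial = k)[k]
}

#' Empirical power at an empirical threshold
#'
#' Proportion of converged alternative-scenario p-values strictly below the
#' threshold derived from the matching null scenario.
#'
#' @param alt_pvalues Alternative-scenario p-values (NA = non-converged).
#' @param threshold Threshold from [empirical_threshold()].
#' @param converged Logical vector; defaults to `!is.na(alt_pvalues)`.
#' @return One-row tibble: `threshold`, `power`, `ci_low`, `ci_high`,
#'   `n_converged`, `n_total`.
#' @export
empirical_power <- function(alt_pvalues, threshold, converged = NULL) {
  if (is.null(converged)) converged <- !is.na(alt_pvalues)
  p <- alt_pvalues[converged & !is.na(alt_pvalues)]
  if (!length(p)) abort("no converged replicates; power undefined")
  k <- sum(p < threshold)
  ci <- wilson_ci(k, length(p))
  tibble(threshold = threshold, power = k / length(p), ci_low = ci[["low"]],
         ci_high = ci[["high"]], n_converged = length(p),
         n_total = length(alt_pvalues))
}

#' Mean bias of converged estimates
#'
#' `mean(estimates - truth)` over non-missing estimates. Under the null the
#' truth is 0 for the logistic (Model B) coefficient; for the NB (Model A)
#' status coefficient the truth is `log(2^log2fc)`.
#'
#' @param estimates Coefficient estimates (NA = non-converged, dropped).
#' @param truth True coefficient value.
#' @return Scalar mean bias.
#' @export
bias <- function(estimates, truth) {
  est <- estimates[!is.na(estimates)]
  if (!length(est)) return(NA_real_)
  mean(est - truth)
}

# fit one simulated replicate with the requested methods; returns a tibble
fit_replicate <- function(y, status, X_cov, methods, dispersion_modes, phi_true) {
  rows <- vector("list", 0L)
  if ("NB" %in% methods) {
    X_a <- cbind(1, status)
    if (!is.null(X_cov)) X_a <- cbind(X_a, X_cov)
    for (mode in dispersion_modes) {
      phi <- switch(mode,
        "TRUE" = phi_true,
        "ML" = disp_ml(y, X_a)$phi,
        "QL" = disp_ql(y, X_a)$phi)
      eng <- if (is.na(phi)) {
        list(coef = c(NA_real_, NA_real_), se = c(NA_real_, NA_real_),
             stat = NA_real_, pvalue = NA_real_, converged = FALSE, n_iter = 0L)
      } else nb_engine(y, X_a, phi)
      rows[[length(rows) + 1L]] <- tibble(
        method = "NB", dispersion_mode = mode, coef = eng$coef[2L],
        se = eng$se[2L], stat = eng$stat, pvalue = eng$pvalue,
        converged = eng$converged)
    }
  }
  logi <- intersect(c("CL", "BL", "FL"), methods)
  if (length(logi)) {
    s <- sd(y)
    if (s == 0) {
      for (m in logi) {
        rows[[length(rows) + 1L]] <- tibble(
          method = m, dispersion_mode = NA_character_, coef = 0, se = Inf,
          stat = 0, pvalue = 1, converged = TRUE)
      }
    } else {
      xs <- (y - mean(y)) / s
      X_b <- cbind(1, xs)
      if (!is.null(X_cov)) X_b <- cbind(X_b, X_cov)
      for (m in logi) {
        eng <- switch(m,
          CL = cl_engine(status, X_b),
          BL = bl_engine(status, X_b),
          FL = fl_engine(status, X_b))
        rows[[length(rows) + 1L]] <- tibble(
          method = m, dispersion_mode = NA_character_, coef = eng$coef[2L] / s,
          se = eng$se[2L] / s, stat = eng$stat, pvalue = eng$pvalue,
          converged = eng$converged)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run all replicates of a scenario
#'
#' For each replicate: simulate counts (and the block's covariates), fit the
#' requested methods, and collect coefficient, standard error, test
#' statistic, p-value and convergence flag. Deterministic given the
#' scenario's seed. Covariate-adjusted models include every simulated
#' covariate in both Model A and Model B.
#'
#' @param sc An [scenario()] object.
#' @param methods Subset of `c("NB", "CL", "BL", "FL")`.
#' @param dispersion_modes Dispersion source(s) for NB fits: any of
#'   `"TRUE"` (the scenario's \eqn{\phi}), `"ML"`, `"QL"`.
#' @return An object of class `fde_eval`; [tidy()] returns the per-replicate
#'   fit tibble, [glance()] per-method convergence fractions.
#' @examples
#' sc <- scenario(n_cases = 10, dispersion = 1, n_reps = 50, seed = 7)
#' ev <- run_scenario(sc, methods = c("NB", "FL"))
#' glance(ev)
#' @export
run_scenario <- function(sc, methods = c("NB", "CL", "BL", "FL"),
                         dispersion_modes = "TRUE") {
  methods <- match.arg(methods, c("NB", "CL", "BL", "FL"), several.ok = TRUE)
  dispersion_modes <- match.arg(dispersion_modes, c("TRUE", "ML", "QL"),
                                several.ok = TRUE)
  status <- status_vector(sc)
  out <- vector("list", sc$n_reps)
  X_cov <- NULL
  for (r in seq_len(sc$n_reps)) {
    if (sc$n_covariates > 0) {
      block <- (r - 1L) %/% 10L
      if (r == 1L || (r - 1L) %% 10L == 0L) {
        X_cov <- simulate_covariates(status, sc$n_covariates, sc$cov_or,
                                     seed = seed_for(sc$seed, 2L, block))
      }
    }
    y <- simulate_counts(status, sc$mu_control, sc$log2fc, sc$dispersion,
                         seed = seed_for(sc$seed, 1L, r))
    rows <- tryCatch(
      fit_replicate(y, status, X_cov, methods, dispersion_modes, sc$dispersion),
      error = function(e) abort(sprintf("replicate %d: %s", r, conditionMessage(e))))
    rows$replicate <- r
    out[[r]] <- rows
  }
  structure(list(scenario = sc, fits = dplyr::bind_rows(out)),
            class = "fde_eval")
}

#' @export
print.fde_eval <- function(x, ...) {
  cat("<fde_eval>\n")
  print(x$scenario)
  print(glance(x))
  invisible(x)
}

#' @rdname run_scenario
#' @param x An `fde_eval` object.
#' @param ... Unused.
#' @export
tidy.fde_eval <- function(x, ...) x$fits

#' @rdname run_scenario
#' @export
glance.fde_eval <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$fits, .data$method, .data$dispersion_mode),
    n_total = dplyr::n(),
    n_converged = sum(.data$converged),
    convergence = mean(.data$converged),
    .groups = "drop")
}

#' Per-method Type-I error summaries of a null-scenario run
#'
#' @param eval An `fde_eval` from a scenario with `log2fc = 0`.
#' @param alphas Nominal levels (defaults to the scenario's).
#' @return Tibble with one row per method x dispersion mode x alpha.
#' @export
scenario_type1 <- function(eval, alphas = NULL) {
  if (eval$scenario$log2fc != 0) {
    abort("Type-I error is defined for null scenarios (log2fc = 0)")
  }
  alphas <- alphas %||% eval$scenario$alphas
  groups <- dplyr::group_split(dplyr::group_by(eval$fits, .data$method,
                                               .data$dispersion_mode))
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(alphas, function(a) {
      dplyr::bind_cols(
        tibble(method = g$method[1], dispersion_mode = g$dispersion_mode[1],
               metric = "type1_error"),
        type1_error(g$pvalue, g$converged, a))
    })
  })
}

same_null_scenario <- function(null_sc, alt_sc) {
  keep <- c("design", "n_cases", "mu_control", "dispersion", "cov_or",
            "n_covariates")
  identical(null_sc[keep], alt_sc[keep]) && null_sc$log2fc == 0 &&
    alt_sc$log2fc > 0
}

#' Empirical power of an alternative run against its matched null run
#'
#' The two runs must agree on every scenario parameter except `log2fc`
#' (null must be 0, alternative positive). For each method and alpha an
#' empirical threshold is computed from the null run's converged p-values
#' and applied to the alternative run.
#'
#' @param null_eval,alt_eval `fde_eval` objects from matched scenarios.
#' @param alphas Nominal levels.
#' @return Tibble with one row per method x dispersion mode x alpha,
#'   including the empirical threshold used.
#' @export
scenario_power <- function(null_eval, alt_eval, alphas = NULL) {
  if (!same_null_scenario(null_eval$scenario, alt_eval$scenario)) {
    abort("null and alternative scenarios differ in parameters other than log2fc")
  }
  alphas <- alphas %||% alt_eval$scenario$alphas
  keys <- dplyr::distinct(alt_eval$fits, .data$method, .data$dispersion_mode)
  purrr::pmap_dfr(keys, function(method, dispersion_mode) {
    pick <- function(fits) {
      fits[fits$method == method &
             identical_or_na(fits$dispersion_mode, dispersion_mode), ]
    }
    nul <- pick(null_eval$fits)
    alt <- pick(alt_eval$fits)
    purrr::map_dfr(alphas, function(a) {
      thr <- empirical_threshold(nul$pvalue[nul$converged], a)
      dplyr::bind_cols(
        tibble(method = method, dispersion_mode = dispersion_mode,
               metric = "empirical_power", alpha = a),
        empirical_power(alt$pvalue, thr, alt$converged))
    })
  })
}

identical_or_na <- function(x, value) {
  if (is.na(value)) is.na(x) else !is.na(x) & x == value
}

#' Per-method bias summaries of a scenario run
#'
#' Truth is `log(2^log2fc)` for the NB status coefficient; for the logistic
#' methods the true coefficient is only known under the null (0), so bias
#' rows for CL/BL/FL are produced only when `log2fc = 0`.
#'
#' @param eval An `fde_eval`.
#' @return Tibble: `method`, `dispersion_mode`, `metric`, `truth`, `value`,
#'   `n_converged`.
#' @export
scenario_bias <- function(eval) {
  lfc <- eval$scenario$log2fc
  groups <- dplyr::group_split(dplyr::group_by(eval$fits, .data$method,
                                               .data$dispersion_mode))
  purrr::map_dfr(groups, function(g) {
    m <- g$method[1]
    if (m != "NB" && lfc != 0) return(NULL)
    truth <- if (m == "NB") log(2^lfc) else 0
    est <- g$coef[g$converged]
    tibble(method = m, dispersion_mode = g$dispersion_mode[1], metric = "bias",
           truth = truth, value = bias(est, truth), n_converged = length(est))
  })
}
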