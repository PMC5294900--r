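# Single-gene simulation engine: NB counts conditional on case-control
# status, plus disease-associated binary covariates regenerated once per
# 10-replicate block.

scenario_menus <- list(
  design = c("balanced", "unbalanced2", "unbalanced4"),
  n_cases = c(10, 25, 75, 500),
  mu_control = c(50, 100, 1000, 10000),
  dispersion = c(0.01, 0.1, 0.5, 1),
  cov_or = c(1, 1.2, 3, 5, 10),
  log2fc = c(0, 0.3, 0.6, 1.2, 2),
  n_covariates = c(0, 1, 2, 3, 5, 10)
)

#' Define a simulation scenario
#'
#' One cell of the simulation parameter grid: study design, number of cases,
#' control mean expression, NB dispersion, covariate odds ratio (CovOR),
#' log2 fold-change and number of binary covariates, plus replication and
#' seed settings. `log2fc = 0` defines a Type-I-error (null) scenario,
#' `log2fc > 0` a power scenario (only up-regulation is simulated). The cell
#' with `n_cases = 10` and `cov_or = 10` is excluded. With `strict = FALSE`
#' parameter values outside the standard menus are accepted.
#'
#' @param design `"balanced"`, `"unbalanced2"` or `"unbalanced4"`; controls
#'   number `n_cases`, `2 * n_cases` or `4 * n_cases` respectively.
#' @param n_cases Number of cases.
#' @param mu_control Mean control expression \eqn{\mu_{D=0}}.
#' @param dispersion NB dispersion \eqn{\phi}.
#' @param cov_or Odds ratio between each binary covariate and status.
#' @param log2fc log2 fold-change; case mean is `2^log2fc * mu_control`.
#' @param n_covariates Number of independent binary covariates.
#' @param n_reps Number of simulation replicates.
#' @param alphas Nominal significance levels.
#' @param seed Master seed for the scenario.
#' @param strict Enforce membership in the standard parameter menus.
#' @return A list of class `fde_scenario`.
#' @export
scenario <- function(design = "balanced", n_cases = 10, mu_control = 1000,
                     dispersion = 0.01, cov_or = 1, log2fc = 0,
                     n_covariates = 0, n_reps = 10000,
                     alphas = c(0.05, 0.01), seed = 1, strict = TRUE) {
  sc <- list(design = design, n_cases = n_cases, mu_control = mu_control,
             dispersion = dispersion, cov_or = cov_or, log2fc = log2fc,
             n_covariates = n_covariates, n_reps = as.integer(n_reps),
             alphas = alphas, seed = as.integer(seed))
  if (strict) {
    for (nm in names(scenario_menus)) {
      if (!sc[[nm]] %in% scenario_menus[[nm]]) {
        abort(sprintf("%s = %s is not in the standard menu (%s); use strict = FALSE to override",
                      nm, format(sc[[nm]]),
                      paste(scenario_menus[[nm]], collapse = ", ")))
      }
    }
  }
  if (sc$n_cases == 10 && sc$cov_or == 10) {
    abort("the combination n_cases = 10, cov_or = 10 is excluded from the grid")
  }
  if (sc$mu_control <= 0 || sc$dispersion < 0 || sc$cov_or <= 0 || sc$log2fc < 0) {
    abort("mu_control and cov_or must be positive; dispersion and log2fc non-negative")
  }
  structure(sc, class = "fde_scenario")
}

#' @export
print.fde_scenario <- function(x, ...) {
  cat(sprintf(paste0("<fde_scenario> %s, n_cases = %d (n = %d), mu_ctl = %g, ",
                     "phi = %g, log2fc = %g, CovOR = %g, %d covariate(s), ",
                     "%d reps, seed %d\n"),
              x$design, x$n_cases, length(status_vector(x)), x$mu_control,
              x$dispersion, x$log2fc, x$cov_or, x$n_covariates, x$n_reps, x$seed))
  invisible(x)
}

#' Case-control status vector for a scenario design
#'
#' Controls first, then cases; unbalanced designs use 2 or 4 controls per
#' case.
#'
#' @param sc An `fde_scenario`.
#' @return Numeric 0/1 vector.
#' @export
status_vector <- function(sc) {
  n_controls <- switch(sc$design,
                       balanced = sc$n_cases,
                       unbalanced2 = 2L * sc$n_cases,
                       unbalanced4 = 4L * sc$n_cases,
                       abort("unknown design"))
  rep(c(0, 1), c(n_controls, sc$n_cases))
}

#' Case mean from control mean and log2 fold-change
#'
#' \eqn{\mu_{D=1} = 2^{\mathrm{log2fc}} \mu_{D=0}}.
#'
#' @param mu_control Control mean, positive.
#' @param log2fc log2 fold-change.
#' @return Case mean.
#' @export
case_mean <- function(mu_control, log2fc) {
  if (any(mu_control <= 0)) abort("mu_control must be positive")
  2^log2fc * mu_control
}

#' Covariate carrier probability in cases
#'
#' Binary covariates are Bernoulli(0.5) in controls and Bernoulli(p) in
#' cases with `p = cov_or / (cov_or + 1)`, so the population odds ratio
#' between covariate and status equals `cov_or`.
#'
#' @param cov_or Covariate-status odds ratio, positive.
#' @return Case carrier probability.
#' @export
covariate_case_prob <- function(cov_or) {
  if (any(cov_or <= 0)) abort("cov_or must be positive")
  cov_or / (cov_or + 1)
}

# deterministic per-stream seeds below 2^31 derived from a master seed
seed_for <- function(master, stream, index = 0) {
  m <- 2147483647
  s <- ((master %% m) * 48271 + (stream %% m) * 69621 + index %% m) %% m
  as.integer(s + 1)
}

#' Simulate NB counts conditional on status
#'
#' Independent draws \eqn{y_i \sim NB(\mu_{D_i}, \phi)} with a common
#' dispersion for cases and controls; \eqn{\phi = 0} draws Poisson counts.
#'
#' @param status 0/1 status vector.
#' @param mu_control,log2fc,dispersion Generative parameters.
#' @param seed Optional seed applied before drawing.
#' @return Integer count vector.
#' @export
simulate_counts <- function(status, mu_control, log2fc = 0, dispersion = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- ifelse(status == 1, case_mean(mu_control, log2fc), mu_control)
  if (dispersion < 1e-12) rpois(length(status), lambda = mu)
  else rnbinom(length(status), mu = mu, size = 1 / dispersion)
}

#' Simulate disease-associated binary covariates
#'
#' Each of `n_covariates` columns is drawn independently as
#' Bernoulli(`covariate_case_prob(cov_or)`) in cases and Bernoulli(0.5) in
#' controls. Columns degenerate in the sample (all 0 or all 1) are redrawn;
#' the number of redraws is attached as attribute `redraws`.
#'
#' @param status 0/1 status vector.
#' @param n_covariates Number of covariates (>= 1).
#' @param cov_or Covariate-status odds ratio.
#' @param seed Optional seed.
#' @param max_redraws Redraw budget per column.
#' @return n x n_covariates 0/1 matrix with columns `X1`, `X2`, ...
#' @export
simulate_covariates <- function(status, n_covariates, cov_or, seed = NULL,
                                max_redraws = 1000) {
  if (n_covariates < 1) abort("n_covariates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(status)
  p <- ifelse(status == 1, covariate_case_prob(cov_or), 0.5)
  redraws <- 0L
  draw <- function() rbinom(n, 1L, p)
  X <- matrix(0L, n, n_covariates,
              dimnames = list(NULL, paste0("X", seq_len(n_covariates))))
  for (j in seq_len(n_covariates)) {
    xj <- draw()
    while (length(unique(xj)) < 2L) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) abort("covariate redraw budget exhausted")
      xj <- draw()
    }
    X[, j] <- xj
  }
  attr(X, "redraws") <- redraws
  X
}

#' Simulate one replicate of a scenario
#'
#' Returns a tidy sample-level tibble: `sample`, `status`, `counts`, and one
#' column per covariate. Covariate matrices are regenerated once per block
#' of 10 replicates (`replicate` 1-10 share a block, 11-20 the next, ...),
#' to incorporate between- and within-covariate-set variability; counts are
#' drawn from a per-replicate stream so any replicate is reproducible in
#' isolation.
#'
#' @param sc An `fde_scenario`.
#' @param replicate Replicate index (1-based).
#' @return Tibble with one row per sample.
#' @export
simulate_dataset <- function(sc, replicate = 1L) {
  status <- status_vector(sc)
  y <- simulate_counts(status, sc$mu_control, sc$log2fc, sc$dispersion,
                       seed = seed_for(sc$seed, 1L, replicate))
  out <- tibble(sample = paste0("s", seq_along(status)), status = status,
                counts = y)
  if (sc$n_covariates > 0) {
    block <- (replicate - 1L) %/% 10L
    X <- simulate_covariates(status, sc$n_covariates, sc$cov_or,
                             seed = seed_for(sc$seed, 2L, block))
    out <- dplyr::bind_cols(out, as_tibble(X))
  }
  out
}

#' Enumerate the scenario grid
#'
#' Cartesian product of the standard parameter menus minus the excluded
#' (`n_cases = 10`, `cov_or = 10`) cells, in a deterministic order. `filter`
#' is a named list restricting any subset of the menus, e.g.
#' `list(n_cases = c(10, 500), log2fc = 0)`.
#'
#' @param filter Named list of menu restrictions.
#' @return Tibble with one row per scenario.
#' @export
scenario_grid <- function(filter = list()) {
  menus <- scenario_menus
  for (nm in names(filter)) {
    if (!nm %in% names(menus)) abort(paste0("unknown scenario field: ", nm))
    bad <- setdiff(filter[[nm]], menus[[nm]])
    if (length(bad)) abort(paste0("values outside menu for ", nm, ": ",
                                  paste(bad, collapse = ", ")))
    menus[[nm]] <- filter[[nm]]
  }
  g <- do.call(tidyr::expand_grid, menus)
  dplyr::filter(g, !(.data$n_cases == 10 & .data$cov_or == 10))
}

#' Generate a multi-gene fixture shaped like a small case-control study
#'
#' Synthetic counts emulating the structure of a small brain RNA-Seq
#' case-control study: genes spread across the five dispersion bins of
#' [dispersion_bin()], a low-expression tail (mean below `low_mean`), a
#' categorical stratum playing the role of an RNA-quality batch variable,
#' and a continuous age-like covariate associated with status. Optionally
#' the first `n_de` genes carry a true fold-change `2^log2fc` in cases.
#' Library sizes are equal by construction.
#'
#' @param n_genes Number of genes (at least 5).
#' @param n_cases,n_controls Group sizes.
#' @param strata_levels Number of stratum levels.
#' @param frac_low Fraction of genes in the low-expression tail.
#' @param low_mean Upper bound of the low-expression tail means.
#' @param n_de Number of differentially expressed genes planted.
#' @param log2fc Fold-change of the planted genes.
#' @param seed Seed.
#' @return List with `counts` (tibble), `phenotype` (tibble: `sample_id`,
#'   `status`, `stratum`, `age`), and `truth` (tibble of per-gene `mu`,
#'   `dispersion`, `log2fc`).
#' @export
make_hd_like_fixture <- function(n_genes = 200, n_cases = 20, n_controls = 49,
                                 strata_levels = 4, frac_low = 0.1,
                                 low_mean = 3, n_de = 0, log2fc = 2,
                                 seed = 1) {
  if (n_genes < 5) abort("n_genes must be at least 5")
  set.seed(seed)
  n <- n_cases + n_controls
  status <- rep(c(0, 1), c(n_controls, n_cases))
  bins <- rbind(c(0.005, 0.05), c(0.05, 0.15), c(0.15, 0.8), c(0.8, 1.5),
                c(1.5, 10))
  bin_idx <- rep_len(seq_len(nrow(bins)), n_genes)
  phi <- exp(stats::runif(n_genes, log(bins[bin_idx, 1]), log(bins[bin_idx, 2])))
  n_low <- max(round(frac_low * n_genes), 0)
  mu <- exp(stats::runif(n_genes, log(10), log(10000)))
  if (n_low > 0) {
    low <- sample.int(n_genes, n_low)
    mu[low] <- stats::runif(n_low, 0.2, low_mean * 0.95)
  }
  g_log2fc <- rep(0, n_genes)
  if (n_de > 0) g_log2fc[seq_len(min(n_de, n_genes))] <- log2fc
  m <- matrix(0L, n_genes, n,
              dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  for (g in seq_len(n_genes)) {
    m[g, ] <- simulate_counts(status, mu[g], g_log2fc[g], phi[g])
  }
  phenotype <- tibble(
    sample_id = colnames(m),
    status = status,
    stratum = paste0("R", sample.int(strata_levels, n, replace = TRUE)),
    age = round(stats::rnorm(n, mean = ifelse(status == 1, 58, 64), sd = 9), 1))
  list(counts = matrix_to_counts(m),
       phenotype = phenotype,
       truth = tibble(gene_id = rownames(m), mu = mu, dispersion = phi,
                      log2fc = g_log2fc,
                      bin = dispersion_bin(phi)))
}
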