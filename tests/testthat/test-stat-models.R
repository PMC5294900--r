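test_that("wald_pvalue matches the normal tail and is monotone in |z|", {
  expect_equal(wald_pvalue(0, 1), 1)
  expect_equal(wald_pvalue(1.959964, 1), 0.05, tolerance = 1e-6)
  z <- seq(0.1, 5, by = 0.3)
  expect_true(all(diff(wald_pvalue(z, 1)) < 0))
  expect_error(wald_pvalue(1, 0), "se")
  expect_error(wald_pvalue(1, -2), "se")
})

test_that("classical logistic matches a brute-force maximizer of its likelihood", {
  for (set in toy_logistic_sets()) {
    d <- data.frame(counts = set$x, status = set$y)
    fit <- fit_classical_logistic(d, expression = "counts")
    # oracle works on the same standardized predictor the fitter uses
    xs <- (set$x - mean(set$x)) / sd(set$x)
    X <- cbind(1, xs)
    beta <- oracle_maximize(function(b) oracle_logit_ll(b, set$y, X), 2)
    expect_equal(fit$coef, beta[2] / sd(set$x), tolerance = 1e-4)
    # expected-information standard error at the oracle optimum
    pr <- plogis(drop(X %*% beta))
    se <- sqrt(diag(solve(crossprod(X, X * (pr * (1 - pr))))))[2] / sd(set$x)
    expect_equal(fit$se, unname(se), tolerance = 1e-4)
    expect_true(fit$converged)
    expect_gte(fit$pvalue, 0)
    expect_lte(fit$pvalue, 1)
  }
})

test_that("Firth logistic matches brute-force maximization of the penalized likelihood", {
  for (set in toy_logistic_sets()) {
    d <- data.frame(counts = set$x, status = set$y)
    fit <- fit_firth_logistic(d)
    xs <- (set$x - mean(set$x)) / sd(set$x)
    X <- cbind(1, xs)
    beta <- oracle_maximize(function(b) oracle_firth_ll(b, set$y, X), 2)
    expect_equal(fit$coef, beta[2] / sd(set$x), tolerance = 1e-4)
  }
})

test_that("Bayes logistic matches brute-force maximization of its posterior", {
  for (set in toy_logistic_sets()) {
    d <- data.frame(counts = set$x, status = set$y)
    fit <- fit_bayes_logistic(d)
    # the fitter standardizes continuous predictors to sd 0.5
    sc <- 2 * sd(set$x)
    xs <- (set$x - mean(set$x)) / sc
    Xs <- cbind(1, xs)
    beta <- oracle_maximize(function(b) oracle_bayes_ll(b, set$y, Xs), 2,
                            starts = list(c(0, 0), c(0, 1), c(0, -1)))
    expect_equal(fit$coef, beta[2] / sc, tolerance = 1e-4)
  }
})

test_that("Firth fit on a separated 2x2 table equals the half-cell-corrected log odds ratio", {
  d <- data.frame(counts = rep(c(1, 0), each = 5), status = rep(c(1, 0), each = 5))
  fit <- fit_firth_logistic(d)
  expect_equal(fit$coef, log((5.5 * 5.5) / (0.5 * 0.5)), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_lt(fit$pvalue, 0.05)
  # cross-check against grid maximization of the penalized likelihood on the
  # standardized predictor scale used internally
  s <- sd(d$counts)
  xs <- (d$counts - mean(d$counts)) / s
  X <- cbind(1, xs)
  grid <- seq(0.1, 5, by = 1e-3)
  ll <- vapply(grid, function(b) oracle_firth_ll(c(0, b), d$status, X), numeric(1))
  expect_equal(fit$coef, grid[which.max(ll)] / s, tolerance = 1e-2)
})

test_that("swapping case and control labels negates the coefficient and keeps p", {
  set.seed(42)
  d <- data.frame(counts = rnbinom(20, mu = 50, size = 2),
                  status = rep(c(0, 1), 10))
  d2 <- d
  d2$status <- 1 - d$status
  for (f in list(fit_classical_logistic, fit_bayes_logistic, fit_firth_logistic)) {
    a <- f(d)
    b <- f(d2)
    expect_equal(a$coef, -b$coef, tolerance = 1e-6)
    expect_equal(a$pvalue, b$pvalue, tolerance = 1e-6)
  }
})

test_that("separation is flagged by CL but yields finite estimates from BL and FL", {
  d <- data.frame(counts = c(100, 110, 120, 10, 20, 30),
                  status = c(1, 1, 1, 0, 0, 0))
  cl <- fit_classical_logistic(d)
  expect_false(cl$converged)
  expect_true(is.na(cl$pvalue))
  bl <- fit_bayes_logistic(d)
  fl <- fit_firth_logistic(d)
  expect_true(bl$converged && is.finite(bl$coef))
  expect_true(fl$converged && is.finite(fl$coef))
})

test_that("a constant expression vector gives a null fit", {
  d <- data.frame(counts = rep(7, 12), status = rep(c(0, 1), 6))
  fit <- fit_classical_logistic(d)
  expect_equal(fit$coef, 0)
  expect_equal(fit$pvalue, 1)
})

test_that("BL converges to CL as the prior scale grows", {
  set.seed(7)
  d <- data.frame(counts = rnorm(60), status = rep(c(0, 1), 30))
  cl <- fit_classical_logistic(d)
  bl <- fit_bayes_logistic(d, prior_scale = 1e7)
  expect_equal(bl$coef, cl$coef, tolerance = 1e-3)
})

test_that("BL shrinks toward zero relative to CL on null data", {
  set.seed(11)
  shrunk <- replicate(100, {
    d <- data.frame(counts = rnbinom(40, mu = 100, size = 2),
                    status = rep(c(0, 1), each = 20))
    cl <- fit_classical_logistic(d)
    bl <- fit_bayes_logistic(d)
    if (!cl$converged) NA else abs(bl$coef) <= abs(cl$coef) + 1e-10
  })
  expect_true(mean(shrunk, na.rm = TRUE) > 0.95)
})

test_that("NB fit on identical groups returns exactly zero", {
  y <- c(5, 9, 13, 5, 9, 13)
  d <- data.frame(counts = y, status = rep(c(0, 1), each = 3))
  fit <- fit_nb_glm(d, dispersion = 0.3)
  expect_equal(fit$coef, 0, tolerance = 1e-10)
})

test_that("NB fit at phi = 0 recovers the closed-form Poisson log rate ratio", {
  set.seed(3)
  status <- rep(c(0, 1), each = 100)
  y <- rpois(200, lambda = ifelse(status == 1, 40, 20))
  d <- data.frame(counts = y, status = status)
  fit <- fit_nb_glm(d, dispersion = 0)
  expect_equal(fit$coef, log(mean(y[status == 1]) / mean(y[status == 0])),
               tolerance = 1e-7)
})

test_that("NB regression recovers the generative log fold-change", {
  set.seed(99)
  status <- rep(c(0, 1), each = 500)
  coefs <- replicate(200, {
    y <- simulate_counts(status, mu_control = 1000, log2fc = 1.2,
                         dispersion = 0.1)
    fit_nb_glm(data.frame(counts = y, status = status), dispersion = 0.1)$coef
  })
  expect_equal(mean(coefs), log(2^1.2), tolerance = 0.01)
})

test_that("NB fit rejects degenerate genes and flags rank-deficient designs", {
  d <- data.frame(counts = rep(0, 10), status = rep(c(0, 1), 5))
  expect_error(fit_nb_glm(d, dispersion = 0.1), "zero")
  d2 <- data.frame(counts = rpois(10, 5), status = rep(c(0, 1), 5))
  d2$dup <- d2$status   # collinear with status
  fit <- fit_nb_glm(d2, covariates = "dup", dispersion = 0.1)
  expect_false(fit$converged)
  expect_true(is.na(fit$pvalue))
})

test_that("tidy and glance return one-row summaries for any fitter", {
  set.seed(5)
  d <- data.frame(counts = rnbinom(30, mu = 50, size = 5),
                  status = rep(c(0, 1), 15))
  tb <- fit_gene(d, dispersion = 0.2)
  expect_equal(nrow(tb), 4)
  expect_setequal(tb$method, c("NB", "CL", "BL", "FL"))
  expect_true(all(tb$pvalue >= 0 & tb$pvalue <= 1, na.rm = TRUE))
  expect_true(all(tb$se[tb$converged] > 0))
  g <- glance(fit_nb_glm(d, dispersion = 0.2))
  expect_equal(g$n, 30L)
  expect_equal(g$n_cases, 15L)
})

test_that("Firth null bias is smaller in magnitude than CL and BL at n = 10 + 10", {
  sc <- scenario(n_cases = 10, dispersion = 1, n_reps = 1000, seed = 31)
  ev <- run_scenario(sc, methods = c("CL", "BL", "FL"))
  f <- tidy(ev)
  mean_coef <- function(m) {
    g <- f[f$method == m & f$converged, ]
    abs(mean(g$coef))
  }
  expect_lt(mean_coef("FL"), mean_coef("CL"))
  expect_lt(mean_coef("FL"), mean_coef("BL"))
})
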