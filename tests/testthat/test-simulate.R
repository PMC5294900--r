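test_that("case_mean applies the log2 fold-change", {
  expect_equal(case_mean(1000, 0), 1000)
  expect_equal(case_mean(1000, 0.3), 2^0.3 * 1000, tolerance = 1e-12)
  expect_equal(case_mean(1000, 0.3), 1231.144, tolerance = 1e-6)
  expect_equal(case_mean(50, 2), 200)
  expect_error(case_mean(0, 1), "positive")
})

test_that("covariate carrier probability reproduces the covariate odds ratio", {
  expect_equal(covariate_case_prob(1), 0.5)
  expect_equal(covariate_case_prob(5), 5 / 6, tolerance = 1e-12)
  p <- covariate_case_prob(3.7)
  expect_equal((p / (1 - p)) / (0.5 / 0.5), 3.7, tolerance = 1e-12)
})

test_that("simulated counts match NB moments and are reproducible", {
  status <- rep(c(0, 1), each = 50000)
  y <- simulate_counts(status, mu_control = 1000, log2fc = 0,
                       dispersion = 0.01, seed = 41)
  expect_true(all(y >= 0) && all(y == round(y)))
  expect_equal(mean(y), 1000, tolerance = 0.01)
  expect_equal(var(y) / mean(y), 1 + 0.01 * 1000, tolerance = 0.1)
  expect_equal(mean(y[status == 1]), mean(y[status == 0]), tolerance = 0.02)
  y2 <- simulate_counts(status, 1000, 0, 0.01, seed = 41)
  expect_identical(y, y2)
  # phi = 0 draws Poisson counts
  yp <- simulate_counts(rep(0, 50000), 100, 0, 0, seed = 42)
  expect_equal(var(yp) / mean(yp), 1, tolerance = 0.05)
})

test_that("only up-regulation is generated", {
  status <- rep(c(0, 1), each = 20000)
  y <- simulate_counts(status, 100, log2fc = 1.2, dispersion = 0.1, seed = 43)
  expect_gt(mean(y[status == 1]), mean(y[status == 0]))
  expect_equal(mean(y[status == 1]) / mean(y[status == 0]), 2^1.2,
               tolerance = 0.05)
})

test_that("covariate blocks are shared across 10 replicates and refresh after", {
  sc <- scenario(n_cases = 25, cov_or = 3, n_covariates = 2, n_reps = 25,
                 seed = 44)
  d1 <- simulate_dataset(sc, 1)
  d10 <- simulate_dataset(sc, 10)
  d11 <- simulate_dataset(sc, 11)
  expect_identical(d1[c("X1", "X2")], d10[c("X1", "X2")])
  expect_false(identical(d1[c("X1", "X2")], d11[c("X1", "X2")]))
  # counts differ between replicates even within a block
  expect_false(identical(d1$counts, d10$counts))
  # full determinism of a replicate in isolation
  expect_identical(simulate_dataset(sc, 7), simulate_dataset(sc, 7))
})

test_that("covariates are independent across columns and exchangeable at cov_or = 1", {
  status <- rep(c(0, 1), each = 250)
  set.seed(45)
  X <- do.call(rbind, lapply(1:40, function(b) {
    simulate_covariates(status, n_covariates = 10, cov_or = 1)
  }))
  cors <- cor(X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  # no association with status at cov_or = 1
  or_hat <- vapply(1:10, function(j) {
    x <- X[, j]
    st <- rep(status, 40)
    (sum(x & st == 1) * sum(!x & st == 0)) /
      (sum(!x & st == 1) * sum(x & st == 0))
  }, numeric(1))
  expect_true(all(abs(log(or_hat)) < 0.15))
  # degenerate columns are redrawn, never returned
  small <- simulate_covariates(rep(c(0, 1), 2), 3, cov_or = 5, seed = 46)
  expect_true(all(apply(small, 2, function(x) length(unique(x)) == 2)))
})

test_that("scenario validation enforces menus and the excluded cell", {
  expect_error(scenario(n_cases = 10, cov_or = 10, n_covariates = 1),
               "excluded")
  expect_error(scenario(n_cases = 12), "menu")
  sc <- scenario(n_cases = 12, strict = FALSE)
  expect_equal(sc$n_cases, 12)
  expect_equal(length(status_vector(scenario(design = "unbalanced2",
                                             n_cases = 25))), 75)
  expect_equal(sum(status_vector(scenario(design = "unbalanced4",
                                          n_cases = 10))), 10)
})

test_that("scenario_grid enumerates the parameter table minus exclusions", {
  t2 <- scenario_grid(list(design = "balanced", mu_control = 1000,
                           log2fc = 0, n_covariates = 0,
                           dispersion = c(0.01, 1), cov_or = 1))
  expect_equal(nrow(t2), 8)
  full <- scenario_grid()
  expected <- 3 * 4 * 4 * 4 * 5 * 5 * 6 - 3 * 4 * 4 * 1 * 5 * 6
  expect_equal(nrow(full), expected)
  expect_identical(full, scenario_grid())
  expect_error(scenario_grid(list(bogus = 1)), "unknown")
  expect_error(scenario_grid(list(n_cases = 11)), "menu")
})

test_that("the multi-gene fixture has the requested structure", {
  fx <- make_hd_like_fixture(n_genes = 50, n_cases = 20, n_controls = 49,
                             seed = 47)
  expect_equal(sum(fx$phenotype$status == 1), 20)
  expect_equal(sum(fx$phenotype$status == 0), 49)
  expect_equal(nrow(fx$counts), 50)
  # all five dispersion bins populated
  expect_equal(length(unique(fx$truth$bin)), 5)
  # low-expression tail present
  expect_gte(sum(fx$truth$mu < 3), 1)
  # reproducible
  fx2 <- make_hd_like_fixture(n_genes = 50, n_cases = 20, n_controls = 49,
                              seed = 47)
  expect_identical(fx$counts, fx2$counts)
  expect_identical(fx$phenotype, fx2$phenotype)
  # planted effects go to the leading genes
  fxd <- make_hd_like_fixture(n_genes = 20, n_de = 2, log2fc = 2, seed = 48)
  expect_equal(fxd$truth$log2fc[1:2], c(2, 2))
  expect_equal(sum(fxd$truth$log2fc > 0), 2)
})
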