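make_counts_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

test_that("stratified permutation conserves within-stratum multisets and fixes phenotypes", {
  set.seed(61)
  m <- matrix(rnbinom(80, mu = 30, size = 2), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  cm <- make_counts_tbl(m)
  strata <- rep(c("A", "B"), each = 5)
  perm <- counts_to_matrix(stratified_permute_counts(cm, strata, seed = 62))
  for (st in unique(strata)) {
    idx <- which(strata == st)
    for (g in 1:8) {
      expect_equal(sort(unname(perm[g, idx])), sort(unname(m[g, idx])))
    }
  }
  # one stratum per sample: nothing can move
  expect_warning(
    ident <- stratified_permute_counts(cm, paste0("u", 1:10), seed = 63),
    "singleton")
  expect_equal(counts_to_matrix(ident), m)
  # a single global stratum is an ordinary per-gene permutation
  glob <- counts_to_matrix(stratified_permute_counts(cm, rep(1, 10), seed = 64))
  expect_false(identical(glob, m))
  expect_equal(t(apply(glob, 1, sort)), t(apply(m, 1, sort)))
  expect_error(stratified_permute_counts(cm, rep("A", 3)), "one label")
})

test_that("exact p-values are (b+1)/(B+1) with ties counted as extreme", {
  nulls <- 1:10000
  expect_equal(exact_pvalue(20000, nulls), 1 / 10001)
  expect_equal(exact_pvalue(rep(5, 3), rep(5, 10)), rep(1, 3))
  set.seed(65)
  obs <- rnorm(50, 2)
  p <- exact_pvalue(obs, rnorm(999))
  expect_true(all(p >= 1 / 1000 & p <= 1))
  expect_equal(exact_pvalue(10, 1:1000, direction = "less"), (10 + 1) / 1001)
  expect_equal(exact_pvalue(-3, c(-4, -2, 1), direction = "abs"), 2 / 4)
})

test_that("DA calibration is the identity on a chi-square(1) null", {
  set.seed(66)
  nulls <- rchisq(5000, 1)
  cal <- null_calibration(nulls, mode = "da")
  expect_equal(cal$scale, 1, tolerance = 0.1)
  obs <- c(0.5, 2, 3.84, 6.63)
  raw <- pchisq(obs, 1, lower.tail = FALSE)
  expect_equal(da_adjust(obs, cal), raw, tolerance = 0.05)
  # empirical mode agrees with exact tail probabilities
  cal_e <- null_calibration(nulls, mode = "exact")
  expect_equal(da_adjust(obs, cal_e), exact_pvalue(obs, nulls))
})

test_that("DA calibration undoes a twofold scale inflation", {
  set.seed(67)
  nulls <- 2 * rchisq(5000, 1)
  cal <- null_calibration(nulls, mode = "da")
  expect_equal(cal$scale, 2, tolerance = 0.15)
  expect_lt(abs(da_adjust(2 * qchisq(0.95, 1), cal) - 0.05), 0.012)
  cal_e <- null_calibration(nulls, mode = "exact")
  expect_lt(abs(da_adjust(2 * qchisq(0.95, 1), cal_e) - 0.05), 0.012)
  expect_error(null_calibration(rchisq(50, 1)), "at least")
  expect_error(null_calibration(c(-1, rchisq(200, 1))), "non-negative")
})

test_that("cross-validated DA holds its size on non-chi-square nulls", {
  set.seed(68)
  # heavy-tailed null: scale mixture, not a scaled chi-square
  nulls <- rchisq(4000, 1) * sample(c(1, 4), 4000, replace = TRUE, prob = c(0.8, 0.2))
  cv <- da_crossval(nulls, alphas = c(0.05, 0.01), seed = 69)
  for (i in seq_len(nrow(cv))) {
    a <- cv$alpha[i]
    expect_lt(abs(cv$rate[i] - a), 3 * sqrt(a * (1 - a) / 4000) + 0.002)
  }
})

test_that("lambda_gc is 1 on the null, scale-equivariant, and works from p-values", {
  set.seed(70)
  stats <- rchisq(20000, 1)
  expect_equal(lambda_gc(stats), 1, tolerance = 0.05)
  expect_equal(lambda_gc(2 * stats), 2 * lambda_gc(stats), tolerance = 1e-12)
  expect_equal(lambda_gc(runif(20000), input = "pvalue"), 1, tolerance = 0.05)
  expect_error(lambda_gc(numeric(0)), "no values")
})

test_that("BH-FDR matches the hand-worked step-up", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  set.seed(71)
  p <- runif(200)^2
  expect_equal(bh_fdr(p)$p_adjusted, oracle_bh(p))
  # an added p = 1 test does not disturb existing adjusted values' order
  r1 <- bh_fdr(p)
  r2 <- bh_fdr(c(p, 1))
  expect_equal(order(r1$p_adjusted), order(r2$p_adjusted[1:200]))
})

test_that("dispersion bins follow the left-closed edges", {
  expect_equal(as.character(dispersion_bin(0.03)), "[0,0.05)")
  expect_equal(as.character(dispersion_bin(0.8)), "[0.8,1.5)")
  expect_equal(as.character(dispersion_bin(5)), "[1.5,10]")
  expect_equal(as.character(dispersion_bin(c(0, 0.05, 0.15, 1.5))),
               c("[0,0.05)", "[0.05,0.15)", "[0.15,0.8)", "[1.5,10]"))
  expect_warning(b <- dispersion_bin(12), "top bin")
  expect_equal(as.character(b), "[1.5,10]")
  expect_error(dispersion_bin(-0.1), "non-negative")
})

test_that("the low-expression filter removes means strictly below the cutoff", {
  # identical samples: size factors are 1, normalized means = raw means
  m <- matrix(rep(c(2.9, 3, 10) * 10, 2), ncol = 2,
              dimnames = list(c("lo", "edge", "hi"), c("a", "b"))) / 10
  m <- round(m * 10)  # counts 29, 30, 100 per sample; means 29, 30, 100
  cm <- make_counts_tbl(m)
  expect_message(kept <- low_expression_filter(cm, min_mean = 30), "removed 1")
  expect_setequal(kept$gene_id, c("edge", "hi"))
  expect_equal(nrow(suppressMessages(low_expression_filter(cm, 0))), 3)
  expect_error(suppressMessages(low_expression_filter(cm, 1e6)), "all genes")
})
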