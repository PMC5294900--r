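# Permutation machinery and data-adaptive (DA) recalibration of test
# statistics, plus inflation diagnostics and FDR control.

#' Stratified per-gene permutation of a count matrix
#'
#' For each gene, expression values are shuffled among samples within each
#' stratum; phenotype columns are untouched, so every status-covariate
#' relationship is preserved while the gene-status association is destroyed
#' within strata. Within-stratum count multisets are conserved exactly.
#' Singleton strata cannot be shuffled and trigger a warning.
#'
#' @inheritParams counts_to_matrix
#' @param strata Vector of stratum labels, one per sample column (in column
#'   order).
#' @param seed Optional seed.
#' @return Permuted counts tibble in the same layout.
#' @export
stratified_permute_counts <- function(counts, strata, gene_id = "gene_id",
                                      seed = NULL) {
  m <- counts_to_matrix(counts, gene_id)
  if (length(strata) != ncol(m)) {
    abort("strata must have one label per sample column")
  }
  if (!is.null(seed)) set.seed(seed)
  groups <- split(seq_len(ncol(m)), strata)
  if (any(lengths(groups) == 1L)) {
    warn("singleton strata present: those samples cannot be shuffled")
  }
  out <- m
  for (idx in groups) {
    if (length(idx) < 2L) next
    for (g in seq_len(nrow(m))) {
      out[g, idx] <- m[g, sample(idx)]
    }
  }
  matrix_to_counts(out, gene_id)
}

#' Exact permutation p-value
#'
#' \eqn{p = (b + 1) / (B + 1)} where `b` counts permutation values at least
#' as extreme as the observed one (ties count as extreme). Always in
#' \[1/(B+1), 1\].
#'
#' @param observed Observed statistic (or p-value with
#'   `direction = "less"`).
#' @param null_values Permutation null values, length B >= 1.
#' @param direction `"greater"` (large values extreme, default for test
#'   statistics), `"less"` (small values extreme, for p-values), or `"abs"`.
#' @return Exact p-value(s); vectorized over `observed`.
#' @export
exact_pvalue <- function(observed, null_values,
                         direction = c("greater", "less", "abs")) {
  direction <- match.arg(direction)
  if (!length(null_values)) abort("null_values must be non-empty")
  B <- length(null_values)
  vapply(observed, function(o) {
    b <- switch(direction,
                greater = sum(null_values >= o),
                less = sum(null_values <= o),
                abs = sum(abs(null_values) >= abs(o)))
    (b + 1) / (B + 1)
  }, numeric(1))
}

#' Build a data-adaptive null calibration
#'
#' The DA method re-estimates the null distribution of test statistics from
#' a modest number of permutation (or null-simulation) statistics instead of
#' trusting the asymptotic reference. In the default `"exact"` mode the
#' empirical null is kept and adjusted p-values are permutation tail
#' probabilities via [exact_pvalue()], which tracks arbitrary null shapes;
#' in `"da"` mode a one-parameter scaled chi-square(1) is fitted by median
#' matching (`scale = median(stats) / qchisq(0.5, 1)`), a smooth
#' approximation appropriate when the null differs from chi-square(1) only
#' by a scale factor.
#' Statistics must be on the 1-df chi-square scale (signed z statistics are
#' squared first via `from = "z"`).
#'
#' @param statistics Null test statistics.
#' @param method Label of the regression method that produced them.
#' @param mode `"exact"` (empirical null, default) or `"da"` (scaled
#'   chi-square fit).
#' @param from `"chisq"` (default) or `"z"`.
#' @param min_size Minimum number of null statistics accepted.
#' @return Object of class `fde_calibration`.
#' @export
null_calibration <- function(statistics, method = "unknown",
                             mode = c("exact", "da"), from = c("chisq", "z"),
                             min_size = 100) {
  mode <- match.arg(mode)
  from <- match.arg(from)
  stats <- statistics[!is.na(statistics)]
  if (from == "z") stats <- stats^2
  if (any(stats < 0)) abort("chi-square scale statistics must be non-negative")
  if (length(stats) < min_size) {
    abort(sprintf("calibration needs at least %d null statistics (got %d)",
                  min_size, length(stats)))
  }
  scale <- median(stats) / qchisq(0.5, df = 1)
  structure(list(method = method, statistics = stats,
                 n_permutations = length(stats), mode = mode, scale = scale),
            class = "fde_calibration")
}

#' @export
print.fde_calibration <- function(x, ...) {
  cat(sprintf("<fde_calibration> %s, mode = %s, B = %d, fitted scale = %.4g\n",
              x$method, x$mode, x$n_permutations, x$scale))
  invisible(x)
}

#' @rdname null_calibration
#' @param x An `fde_calibration` object.
#' @param ... Unused.
#' @export
glance.fde_calibration <- function(x, ...) {
  tibble(method = x$method, mode = x$mode, n_permutations = x$n_permutations,
         scale = x$scale)
}

#' Data-adaptive adjusted p-values
#'
#' Recomputes each observed statistic's p-value against the recalibrated
#' null: the survival function of the fitted scaled chi-square(1) in `"da"`
#' mode, or the exact empirical tail probability in `"exact"` mode.
#'
#' @param observed_stats Observed statistics on the same scale as the
#'   calibration (chi-square 1 df; use `from = "z"` to square signed z).
#' @param calibration An [null_calibration()] object.
#' @param from `"chisq"` or `"z"`.
#' @return Adjusted p-values in (0, 1\].
#' @export
da_adjust <- function(observed_stats, calibration, from = c("chisq", "z")) {
  from <- match.arg(from)
  if (!inherits(calibration, "fde_calibration")) {
    abort("calibration must be an fde_calibration object")
  }
  s <- observed_stats
  if (from == "z") s <- s^2
  if (calibration$mode == "da") {
    pchisq(s / calibration$scale, df = 1, lower.tail = FALSE)
  } else {
    exact_pvalue(s, calibration$statistics, direction = "greater")
  }
}

#' Cross-validated Type-I error of the DA adjustment
#'
#' K-fold validation of the data-adaptive recalibration on a set of null
#' statistics: each fold's statistics are adjusted with a calibration fitted
#' on the remaining folds, and the pooled rejection rate at each alpha is
#' reported. This measures the out-of-sample size of the DA method.
#'
#' @param statistics Null statistics (chi-square scale; `from = "z"` to
#'   square signed z statistics).
#' @param alphas Nominal levels.
#' @param k Number of folds.
#' @param from `"chisq"` or `"z"`.
#' @param mode Calibration mode passed to [null_calibration()].
#' @param seed Seed for the fold split.
#' @return Tibble: `alpha`, `rate`, `ci_low`, `ci_high`, `n`.
#' @export
da_crossval <- function(statistics, alphas = c(0.05, 0.01), k = 5,
                        from = c("chisq", "z"), mode = c("exact", "da"),
                        seed = 1) {
  from <- match.arg(from)
  mode <- match.arg(mode)
  s <- statistics[!is.na(statistics)]
  if (from == "z") s <- s^2
  if (length(s) < k * 20) abort("too few null statistics for cross-validation")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(s)))
  p <- numeric(length(s))
  for (f in seq_len(k)) {
    cal <- null_calibration(s[fold != f], mode = mode)
    p[fold == f] <- da_adjust(s[fold == f], cal)
  }
  purrr::map_dfr(alphas, function(a) {
    kk <- sum(p < a)
    ci <- wilson_ci(kk, length(p))
    tibble(alpha = a, rate = kk / length(p), ci_low = ci[["low"]],
           ci_high = ci[["high"]], n = length(p))
  })
}

#' Genomic inflation factor
#'
#' \eqn{\lambda_{gc}}: the median observed 1-df chi-square statistic divided
#' by the null median `qchisq(0.5, 1)` (0.4549364). P-values are converted
#' to chi-square quantiles first. Values above 1 suggest inflation of the
#' test statistics.
#'
#' @param x Statistics or p-values.
#' @param input `"statistic"` (default) or `"pvalue"`.
#' @return Scalar \eqn{\lambda_{gc}}.
#' @export
lambda_gc <- function(x, input = c("statistic", "pvalue")) {
  input <- match.arg(input)
  x <- x[!is.na(x)]
  if (!length(x)) abort("no values supplied")
  stats <- if (input == "pvalue") qchisq(x, df = 1, lower.tail = FALSE) else x
  median(stats) / qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted p-values and discovery flags at level `q`.
#'
#' @param pvalues Raw p-values.
#' @param q FDR level in (0, 1).
#' @return Tibble: `pvalue`, `p_adjusted`, `significant`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)")
  adj <- p.adjust(pvalues, method = "BH")
  tibble(pvalue = pvalues, p_adjusted = adj,
         significant = !is.na(adj) & adj <= q)
}

disp_bin_breaks <- c(0, 0.05, 0.15, 0.8, 1.5, 10)
disp_bin_labels <- c("[0,0.05)", "[0.05,0.15)", "[0.15,0.8)", "[0.8,1.5)",
                     "[1.5,10]")

#' Dispersion category of a gene
#'
#' Genes are grouped into five dispersion bins with edges 0, 0.05, 0.15,
#' 0.8, 1.5, 10 (left-closed); genes with dispersion above 0.8 are "largely
#' dispersed". Values of 10 or more map to the top bin with a warning.
#'
#' @param gene_dispersion Non-negative dispersion value(s).
#' @return Factor with the five bin labels.
#' @export
dispersion_bin <- function(gene_dispersion) {
  if (any(is.na(gene_dispersion)) || any(gene_dispersion < 0)) {
    abort("dispersion must be non-negative")
  }
  if (any(gene_dispersion >= 10)) {
    warn("dispersion values >= 10 mapped to the top bin [1.5,10]")
  }
  idx <- findInterval(gene_dispersion, disp_bin_breaks,
                      rightmost.closed = TRUE)
  idx <- pmin(idx, length(disp_bin_labels))
  factor(disp_bin_labels[idx], levels = disp_bin_labels)
}

#' Remove lowly expressed genes
#'
#' Drops genes whose mean normalized expression is strictly below
#' `min_mean` (default 3). Normalization (median-of-ratios) is applied
#' before computing means unless `normalize = FALSE`; the returned counts
#' are the original (unnormalized) rows of the retained genes. The number
#' of removed genes is reported with a message.
#'
#' @inheritParams counts_to_matrix
#' @param min_mean Minimum mean normalized expression (>= 0).
#' @param normalize Compute means on normalized counts (default TRUE).
#' @return Filtered counts tibble.
#' @export
low_expression_filter <- function(counts, min_mean = 3, normalize = TRUE,
                                  gene_id = "gene_id") {
  if (min_mean < 0) abort("min_mean must be >= 0")
  m <- counts_to_matrix(counts, gene_id)
  basis <- if (normalize) counts_to_matrix(normalize_counts(counts,
                                                            gene_id = gene_id),
                                           gene_id) else m
  keep <- rowMeans(basis) >= min_mean
  if (!any(keep)) abort("all genes fall below min_mean")
  inform(sprintf("low_expression_filter: removed %d of %d genes (mean < %g)",
                 sum(!keep), length(keep), min_mean))
  counts[keep, , drop = FALSE]
}
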