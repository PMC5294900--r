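# Real-data pipeline: normalize, filter, fit per gene, optionally
# recalibrate against stratified-permutation nulls, control FDR.

stat_to_chisq <- function(stat, stat_type) {
  ifelse(stat_type == "chisq", stat, stat^2)
}

# fit one gene with one method; x_pred is the logistic predictor (normalized
# or raw counts), y_raw the raw counts for the NB model
fit_gene_method <- function(method, y_raw, x_pred, d, X_cov, offset, phi) {
  if (method == "NB") {
    X_a <- cbind(1, d)
    if (!is.null(X_cov)) X_a <- cbind(X_a, X_cov)
    eng <- nb_engine(y_raw, X_a, phi, offset = offset)
    return(list(coef = eng$coef[2L], se = eng$se[2L], stat = eng$stat,
                stat_type = "z", pvalue = eng$pvalue, converged = eng$converged))
  }
  s <- sd(x_pred)
  if (s == 0) {
    return(list(coef = 0, se = Inf, stat = 0,
                stat_type = if (method == "FL") "chisq" else "z",
                pvalue = 1, converged = TRUE))
  }
  xs <- (x_pred - mean(x_pred)) / s
  X_b <- cbind(1, xs)
  if (!is.null(X_cov)) X_b <- cbind(X_b, X_cov)
  eng <- switch(method,
                CL = cl_engine(d, X_b),
                BL = bl_engine(d, X_b),
                FL = fl_engine(d, X_b))
  list(coef = eng$coef[2L] / s, se = eng$se[2L] / s, stat = eng$stat,
       stat_type = if (method == "FL") "chisq" else "z",
       pvalue = eng$pvalue, converged = eng$converged)
}

analyze_matrix <- function(m_raw, m_pred, d, X_cov, offset, methods,
                           dispersion) {
  genes <- rownames(m_raw)
  rows <- vector("list", length(genes) * length(methods))
  k <- 0L
  for (g in seq_along(genes)) {
    y_raw <- m_raw[g, ]
    X_a <- cbind(1, d)
    if (!is.null(X_cov)) X_a <- cbind(X_a, X_cov)
    phi <- if (all(y_raw == 0)) NA_real_ else {
      est <- if (dispersion == "ML") disp_ml(y_raw, X_a, offset = offset)
             else disp_ql(y_raw, X_a, offset = offset)
      est$phi
    }
    for (method in methods) {
      k <- k + 1L
      f <- if (is.na(phi) && method == "NB") {
        list(coef = NA_real_, se = NA_real_, stat = NA_real_, stat_type = "z",
             pvalue = NA_real_, converged = FALSE)
      } else {
        fit_gene_method(method, y_raw, m_pred[g, ], d, X_cov, offset, phi)
      }
      rows[[k]] <- tibble(gene_id = genes[g], method = method,
                          coef = f$coef, se = f$se, stat = f$stat,
                          stat_type = f$stat_type, pvalue = f$pvalue,
                          converged = f$converged, dispersion = phi)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-gene differential-expression analysis of a count matrix
#'
#' Runs the requested regression methods on every gene of a count matrix:
#' NB regression of counts on status (with median-of-ratios size factors as
#' log offsets) and/or logistic regressions of status on expression (the
#' normalized count as predictor, per-count coefficients). Optionally the
#' p-values are recalibrated with the data-adaptive (DA) method against
#' `n_permutations` stratified permutations of the matrix, and
#' Benjamini-Hochberg FDR control at level `fdr_q` is applied per method
#' (to the DA-adjusted p-values when present, otherwise to the raw ones).
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param phenotype Phenotype tibble with `sample_id`, `status` and any
#'   covariate/stratum columns; joined to the counts by id.
#' @param methods Subset of `c("NB", "CL", "BL", "FL")`.
#' @param covariates Phenotype column names entering every gene's model.
#' @param dispersion `"ML"` or `"QL"` per-gene dispersion estimation for NB.
#' @param expression `"normalized"` (default; the real-data convention) or
#'   `"raw"` counts as the logistic predictor.
#' @param min_mean Low-expression filter threshold on the mean normalized
#'   count (0 disables).
#' @param n_permutations Number of stratified permutations for the DA
#'   recalibration (0 disables).
#' @param strata Phenotype column defining permutation strata (`NULL` = one
#'   global stratum).
#' @param da_mode `"exact"` (empirical permutation tail, default) or
#'   `"da"` (scaled chi-square fit).
#' @param pool `"bin"` to pool permutation nulls within dispersion bins
#'   (falls back to `"all"` when a bin has too few statistics) or `"all"`.
#' @param fdr_q FDR level.
#' @param seed Seed for the permutations.
#' @return A tibble of class `fde_results`, one row per gene x method, with
#'   coefficient, SE, statistic, p-values (`pvalue`, optionally `p_da`),
#'   `p_adjusted`, `significant`, convergence flag, dispersion estimate and
#'   bin, and mean normalized expression. [glance()] summarises
#'   \eqn{\lambda_{gc}} and convergence per method.
#' @export
analyze <- function(counts, phenotype, methods = c("NB", "FL"),
                    covariates = NULL, dispersion = c("ML", "QL"),
                    expression = c("normalized", "raw"), min_mean = 0,
                    n_permutations = 0, strata = NULL,
                    da_mode = c("exact", "da"), pool = c("bin", "all"),
                    fdr_q = 0.05, seed = 1) {
  methods <- match.arg(methods, c("NB", "CL", "BL", "FL"), several.ok = TRUE)
  dispersion <- match.arg(dispersion)
  expression <- match.arg(expression)
  da_mode <- match.arg(da_mode)
  pool <- match.arg(pool)

  ph <- align_samples(counts, phenotype)
  d <- check_status(ph$status)
  X_cov <- if (length(covariates)) pull_cols(ph, covariates) else NULL
  if (min_mean > 0) counts <- low_expression_filter(counts, min_mean)

  sf <- size_factors(counts)
  norm <- counts_to_matrix(normalize_counts(counts, sf))
  m_raw <- counts_to_matrix(counts)
  offset <- log(sf$size_factor[match(colnames(m_raw), sf$sample_id)])
  m_pred <- if (expression == "normalized") norm else m_raw

  res <- analyze_matrix(m_raw, m_pred, d, X_cov, offset, methods, dispersion)
  res$dispersion_bin <- factor(NA_character_, levels = disp_bin_labels)
  ok <- !is.na(res$dispersion)
  res$dispersion_bin[ok] <- dispersion_bin(pmin(pmax(res$dispersion[ok], 0),
                                                9.999))
  res$mean_expression <- rowMeans(norm)[match(res$gene_id, rownames(norm))]

  if (n_permutations > 0) {
    strata_vec <- if (is.null(strata)) rep(1L, ncol(m_raw)) else {
      if (!strata %in% names(ph)) abort(paste0("no '", strata, "' column in phenotype"))
      ph[[strata]][match(colnames(m_raw), ph$sample_id)]
    }
    null_rows <- vector("list", n_permutations)
    for (b in seq_len(n_permutations)) {
      perm <- counts_to_matrix(
        stratified_permute_counts(matrix_to_counts(m_raw), strata_vec,
                                  seed = seed_for(seed, 3L, b)))
      perm_pred <- if (expression == "normalized") {
        sweep(perm, 2L, exp(offset), `/`)
      } else perm
      pr <- analyze_matrix(perm, perm_pred, d, X_cov, offset, methods,
                           dispersion)
      pr$perm <- b
      null_rows[[b]] <- pr
    }
    nulls <- dplyr::bind_rows(null_rows)
    nulls$dispersion_bin <- factor(NA_character_, levels = disp_bin_labels)
    nok <- !is.na(nulls$dispersion)
    nulls$dispersion_bin[nok] <- dispersion_bin(pmin(pmax(nulls$dispersion[nok],
                                                          0), 9.999))
    nulls$chisq <- stat_to_chisq(nulls$stat, nulls$stat_type)
    res$chisq <- stat_to_chisq(res$stat, res$stat_type)
    res$p_da <- NA_real_
    for (method in methods) {
      obs_i <- which(res$method == method & res$converged)
      nul_m <- nulls[nulls$method == method & nulls$converged &
                       !is.na(nulls$chisq), ]
      if (!nrow(nul_m) || !length(obs_i)) next
      groups <- if (pool == "bin") split(obs_i, res$dispersion_bin[obs_i])
                else list(all = obs_i)
      if (pool == "bin") {
        nul_bins <- split(nul_m$chisq, nul_m$dispersion_bin)
        small <- vapply(names(groups)[lengths(groups) > 0],
                        function(bn) length(nul_bins[[bn]]) < 100, logical(1))
        if (any(small)) {
          inform("analyze: some dispersion bins have < 100 null statistics; pooling all bins")
          groups <- list(all = obs_i)
        }
      }
      for (bn in names(groups)) {
        idx <- groups[[bn]]
        if (!length(idx)) next
        nv <- if (bn == "all") nul_m$chisq else
          nul_m$chisq[nul_m$dispersion_bin == bn]
        cal <- null_calibration(nv, method = method, mode = da_mode)
        res$p_da[idx] <- da_adjust(res$chisq[idx], cal)
      }
    }
    res$chisq <- NULL
  }

  base_p <- if ("p_da" %in% names(res)) dplyr::coalesce(res$p_da, res$pvalue)
            else res$pvalue
  res$p_adjusted <- NA_real_
  for (method in unique(res$method)) {
    i <- res$method == method
    res$p_adjusted[i] <- p.adjust(base_p[i], method = "BH")
  }
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted <= fdr_q

  structure(res, class = c("fde_results", class(res)),
            seed = seed, fdr_q = fdr_q, n_permutations = n_permutations)
}

#' @rdname analyze
#' @param x An `fde_results` tibble.
#' @param ... Unused.
#' @export
glance.fde_results <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$method),
    n_genes = dplyr::n(),
    n_converged = sum(.data$converged),
    lambda_gc = lambda_gc(stat_to_chisq(.data$stat[.data$converged],
                                        .data$stat_type[.data$converged])),
    n_significant = sum(.data$significant),
    .groups = "drop")
}

#' Write analysis results, run summary, and QQ-plot data
#'
#' Writes `results.tsv` (the full per-gene table), `summary.json` (seed,
#' package version, per-method convergence counts and, when at least 100
#' genes were analyzed, \eqn{\lambda_{gc}}), and per-method
#' `qq_<method>.tsv` files of expected vs observed -log10 p-value pairs
#' sorted by expected quantile.
#'
#' @param results An `fde_results` tibble from [analyze()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(as_tibble(results), file.path(dir, "results.tsv"))
  g <- glance.fde_results(results)
  n_genes <- length(unique(results$gene_id))
  summ <- list(
    package_version = as.character(utils::packageVersion("firthde")),
    seed = attr(results, "seed"),
    n_permutations = attr(results, "n_permutations"),
    fdr_q = attr(results, "fdr_q"),
    methods = lapply(split(g, g$method), function(r) {
      out <- list(n_genes = r$n_genes, n_converged = r$n_converged,
                  n_significant = r$n_significant)
      if (n_genes >= 100) out$lambda_gc <- r$lambda_gc
      out
    }))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (method in unique(results$method)) {
    r <- results[results$method == method & !is.na(results$pvalue), ]
    p <- sort(r$pvalue)
    qq <- tibble(expected = -log10(ppoints(length(p))),
                 observed = -log10(p))
    qq <- qq[order(qq$expected), ]
    readr::write_tsv(qq, file.path(dir, paste0("qq_", method, ".tsv")))
  }
  invisible(dir)
}
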