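# ggplot2 graphics for the main result types.

#' @rdname run_scenario
#' @param object An `fde_eval` object.
#' @param alphas Nominal levels to display (null scenarios only).
#' @export
autoplot.fde_eval <- function(object, alphas = NULL, ...) {
  if (object$scenario$log2fc != 0) {
    abort("autoplot.fde_eval displays Type-I error; use a null scenario run")
  }
  s <- scenario_type1(object, alphas)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$method, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~alpha, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Type-I error rate",
                  title = "Empirical Type-I error with Wilson 95% CI")
}

#' @rdname analyze
#' @param object An `fde_results` tibble.
#' @export
autoplot.fde_results <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$pvalue), ]
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$method),
    expected = -log10(ppoints(dplyr::n()))[rank(.data$pvalue,
                                                ties.method = "first")],
    observed = -log10(.data$pvalue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = "QQ plot of per-gene p-values")
}

#' Power curves across matched scenario pairs
#'
#' Plots the output of one or more [scenario_power()] calls (row-bound, with
#' added columns for the varying parameter, e.g. `log2fc`).
#'
#' @param power_tbl Tibble from [scenario_power()] with an added `x` column.
#' @param x Name of the column to place on the x axis.
#' @return A ggplot object.
#' @export
plot_power <- function(power_tbl, x = "log2fc") {
  ggplot2::ggplot(power_tbl,
                  ggplot2::aes(x = .data[[x]], y = .data$power,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "Empirical power")
}
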