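#' Plot a calibration model
#'
#' The empirical relative-variance grid (one point per simulated MAF/r
#' condition, bivariate-normal reference at 1) with the fitted inflation
#' curve `f(z)` overlaid.
#'
#' @param object A `coassoc_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coassoc_calibration <- function(object, ...) {
  grid <- object$grid
  zz <- seq(0, max(abs(grid$z_bar)), length.out = 200)
  curve_df <- tibble(z = zz, f = predict_f(object, zz))
  ggplot2::ggplot(grid, ggplot2::aes(x = abs(.data$z_bar), y = .data$rel_var)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$maf1)), alpha = 0.7) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(x = .data$z, y = .data$f),
                       linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "|Fisher z| of pooled correlation",
                  y = "relative variance of z-hat  (units of 1/(n-3))",
                  colour = "MAF1",
                  title = "Empirical variance inflation of the Fisher z estimate") +
    ggplot2::theme_minimal()
}

#' Plot an experiment table
#'
#' Rejection-rate curves with 95% Monte-Carlo error bars, faceted the way
#' the experiment is structured (sample size or correlation for the type-I
#' tables, swept parameter x main effects for power curves, odds ratio x
#' arm for the LD study).
#'
#' @param object A `coassoc_experiment` tibble.
#' @param alpha Nominal level drawn as a dashed reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coassoc_experiment <- function(object, alpha = 0.05, ...) {
  kind <- attr(object, "experiment")
  d <- as_tibble(object)
  xvar <- switch(kind,
    type1_main_effects = "n_sample",
    type1_correlation = "r",
    power_curves = NULL,
    ld_effect = "or",
    "n_sample")
  if (kind == "power_curves") {
    d$x <- ifelse(d$panel %in% c("a", "d"), d$beta3, d$r)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$rate,
                                         colour = .data$statistic,
                                         linetype = .data$main_effects)) +
      ggplot2::facet_wrap(~ panel, scales = "free_x") +
      ggplot2::labs(x = "swept parameter (interaction beta3 or correlation r)")
  } else if (kind == "ld_effect") {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$rate,
                                         colour = .data$statistic)) +
      ggplot2::facet_wrap(~ arm, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "odds ratio of the (first) causal SNP")
  } else {
    if (kind == "type1_main_effects") {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$rate,
                                           colour = .data$statistic,
                                           linetype = .data$main_effects))
    } else {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$rate,
                                           colour = .data$statistic,
                                           linetype = factor(.data$n_sample)))
    }
    p <- p + ggplot2::labs(x = xvar)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - 1.96 * .data$mc_se,
                                        ymax = .data$rate + 1.96 * .data$mc_se),
                           width = 0) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(y = sprintf("rejection rate at alpha = %g", alpha),
                  title = paste("Experiment:", kind)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a pairwise scan
#'
#' Case-control correlation difference against `-log10 p` for one chosen
#' statistic; skipped pairs are omitted.
#'
#' @param object A [coassoc_scan()] result.
#' @param statistic Which p-value column to use (default the calibrated
#'   fast test if present).
#' @param alpha Significance threshold line (raw scale).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coassoc_scan <- function(object, statistic = NULL, alpha = 1e-4, ...) {
  cfg <- attr(object, "config")
  statistic <- statistic %||%
    (if ("calib" %in% cfg$stats) "calib" else cfg$stats[1])
  pcol <- paste0("p_", statistic)
  d <- dplyr::filter(as_tibble(object), !is.na(.data[[pcol]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_case - .data$r_ctrl,
                                  y = -log10(.data[[pcol]]))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "r(case) - r(control)",
                  y = expression(-log[10](p)),
                  title = sprintf("Pairwise co-association scan (%s statistic)", statistic)) +
    ggplot2::theme_minimal()
}
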