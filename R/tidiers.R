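#' Tidy a calibration model
#'
#' One row per coefficient of the log-variance fit `log f(z) = a + b|z| +
#' c z^2`.
#'
#' @param x A `coassoc_calibration`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.coassoc_calibration <- function(x, ...) {
  tibble(term = c("(Intercept)", "abs(z)", "z^2"),
         estimate = as.numeric(x$coef))
}

#' @rdname tidy.coassoc_calibration
#' @export
glance.coassoc_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma,
         n_grid = nrow(x$grid), n_cal = x$n_cal, reps_cal = x$reps_cal,
         z_max = x$z_range[2], seed = x$seed, version = x$version)
}

#' Summarise a pairwise scan
#'
#' @param x A [coassoc_scan()] result.
#' @param ... Unused.
#' @return A one-row tibble: pair counts, skip counts, and the smallest
#'   p-value per statistic.
#' @export
glance.coassoc_scan <- function(x, ...) {
  cfg <- attr(x, "config")
  out <- tibble(n_snps = cfg$n_snps, n_pairs = nrow(x),
                n_skipped = sum(!is.na(x$skip_reason)))
  for (s in cfg$stats) {
    out[[paste0("min_p_", s)]] <- suppressWarnings(min(x[[paste0("p_", s)]], na.rm = TRUE))
  }
  out
}

#' Summarise an experiment table
#'
#' @param x A `coassoc_experiment` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the experiment name, condition count, and
#'   rejection-rate range per statistic.
#' @export
glance.coassoc_experiment <- function(x, ...) {
  rng <- dplyr::summarise(dplyr::group_by(as_tibble(x), .data$statistic),
                          min_rate = min(.data$rate), max_rate = max(.data$rate))
  tibble(experiment = attr(x, "experiment"),
         n_conditions = nrow(x) / dplyr::n_distinct(x$statistic),
         statistics = paste(rng$statistic, collapse = ","),
         min_rate = min(rng$min_rate), max_rate = max(rng$max_rate))
}
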