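# Empirical calibration of the fast co-association test.
#
# Fisher's z-difference assumes Var(z-hat) = 1/(n-3), exact under bivariate
# normality. Genotype counts are not bivariate normal: as the inter-SNP
# correlation grows, the true Var(z-hat) drifts away from 1/(n-3). The
# calibrated test keeps the 1/(n-3) skeleton and multiplies it by
# f(z_pooled) = exp(b|z| + c z^2), with (b, c) fitted once by least squares
# of log relative variance on |z| and z^2 over a simulated corpus of SNP
# pairs spanning MAFs and correlations. The fit has no intercept: at
# independence the relative variance is 1 up to O(1/n) for any counting
# margins, so f(0) = 1 is imposed rather than estimated and the calibrated
# statistic coincides with the plain Fisher test for uncorrelated pairs.

#' Empirical relative-variance grid for calibration
#'
#' For every feasible (MAF pair, target r) condition, simulates `reps_cal`
#' independent genotype pairs of `n_cal` individuals, computes the Fisher
#' z of the sample correlation in each, and records the relative variance
#' `Var(z-hat) * (n_cal - 3)` (so 1 is the bivariate-normal reference)
#' against the mean z. Infeasible correlations for a MAF pair are skipped
#' with a warning.
#'
#' @param maf_pairs Data frame with columns `maf1`, `maf2`, or `NULL` for
#'   all unordered pairs over `{0.1, 0.2, 0.3, 0.4, 0.5}`.
#' @param r_grid Target correlations (default spans 0 to 0.95).
#' @param n_cal Individuals per simulated pair.
#' @param reps_cal Replicates per grid condition.
#' @param seed Integer seed; the grid is reproducible bit-for-bit.
#' @return A tibble with columns `maf1`, `maf2`, `r_target`, `z_bar`
#'   (mean Fisher z over replicates), `rel_var`, `n_cal`, `reps_cal`.
#' @export
empirical_variance_grid <- function(maf_pairs = NULL,
                                    r_grid = c(0, 0.15, 0.3, 0.45, 0.6, 0.75, 0.9, 0.95),
                                    n_cal = 10000, reps_cal = 500, seed = 1L) {
  if (is.null(maf_pairs)) {
    mafs <- seq(0.1, 0.5, by = 0.1)
    maf_pairs <- expand.grid(maf1 = mafs, maf2 = mafs)
    maf_pairs <- maf_pairs[maf_pairs$maf1 <= maf_pairs$maf2, ]
  }
  stopifnot(n_cal > 100, reps_cal >= 20)
  conds <- tidyr::expand_grid(as_tibble(maf_pairs), r_target = r_grid)
  withr::with_seed(seed, {
    rows <- purrr::pmap(conds, function(maf1, maf2, r_target) {
      rho <- tryCatch(solve_latent_rho(r_target, maf1, maf2),
        coassoc_infeasible_correlation = function(e) {
          coassoc_warn("infeasible_correlation",
            sprintf("skipping infeasible grid point maf %.2f/%.2f r %.2f",
                    maf1, maf2, r_target))
          NULL
        })
      if (is.null(rho)) return(NULL)
      # all replicates in one latent matrix; per-replicate r via column sums
      z1 <- matrix(rnorm(n_cal * reps_cal), n_cal, reps_cal)
      z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(rnorm(n_cal * reps_cal), n_cal, reps_cal)
      g1 <- cut_latent(z1, maf1); dim(g1) <- dim(z1)
      g2 <- cut_latent(z2, maf2); dim(g2) <- dim(z2)
      r_hat <- colsum_cor(g1, g2)
      r_hat <- pmin(pmax(r_hat, -(1 - 1e-8)), 1 - 1e-8)
      z_hat <- atanh(r_hat)
      tibble(maf1 = maf1, maf2 = maf2, r_target = r_target,
             z_bar = mean(z_hat), rel_var = var(z_hat) * (n_cal - 3),
             n_cal = n_cal, reps_cal = reps_cal)
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  out
}

# columnwise Pearson correlation of two equally shaped matrices
colsum_cor <- function(a, b) {
  n <- nrow(a)
  sa <- colSums(a); sb <- colSums(b)
  num <- colSums(a * b) - sa * sb / n
  den <- sqrt((colSums(a^2) - sa^2 / n) * (colSums(b^2) - sb^2 / n))
  num / den
}

#' Fit the log-variance calibration model
#'
#' Least squares of `log(rel_var)` on `|z_bar|` and `z_bar^2` (no
#' intercept) over an [empirical_variance_grid()]. Evenness in z is built
#' into the regressors, since the sign of a correlation is arbitrary (it
#' flips with the allele counted); the missing intercept pins `f(0) = 1`,
#' the provable relative variance of independent pairs, so the calibrated
#' statistic reduces to the plain Fisher test at independence. The stored
#' coefficient vector keeps an explicit `a = 0` slot.
#'
#' @param grid An [empirical_variance_grid()] tibble (>= 10 points, >= 3
#'   distinct `z_bar`).
#' @return A `coassoc_calibration` object holding coefficients `a`, `b`,
#'   `c`, the fit diagnostics, the grid, and the fitted z range.
#' @export
fit_logvar <- function(grid) {
  stopifnot(nrow(grid) >= 10)
  if (length(unique(round(grid$z_bar, 10))) < 3) {
    coassoc_abort("rank_deficient", "calibration grid has fewer than 3 distinct z values")
  }
  az <- abs(grid$z_bar)
  fit <- lm(log(rel_var) ~ 0 + az + I(az^2), data = grid)
  new_calibration(
    coef = setNames(c(0, as.numeric(coef(fit))), c("a", "b", "c")),
    grid = as_tibble(grid),
    r_squared = summary(fit)$r.squared,
    sigma = summary(fit)$sigma,
    z_range = range(abs(grid$z_bar)),
    n_cal = grid$n_cal[1], reps_cal = grid$reps_cal[1],
    seed = attr(grid, "seed") %||% NA_integer_
  )
}

new_calibration <- function(coef, grid, r_squared, sigma, z_range,
                            n_cal, reps_cal, seed) {
  structure(list(coef = coef, grid = grid, r_squared = r_squared,
                 sigma = sigma, z_range = z_range,
                 n_cal = as.integer(n_cal), reps_cal = as.integer(reps_cal),
                 seed = seed,
                 version = as.character(packageVersion("coassoc"))),
            class = "coassoc_calibration")
}

#' Variance-inflation multiplier f(z)
#'
#' Evaluates `exp(a + b |z| + c z^2)` from a fitted calibration model
#' (`a = 0` for models fitted by [fit_logvar()], so `f(0) = 1`). Even in
#' `z` and strictly positive by construction. Values of `|z|` outside the
#' fitted range extrapolate, with a warning (once per call).
#'
#' @param calibration A `coassoc_calibration`.
#' @param z Pooled-sample Fisher z value(s).
#' @return Multiplier(s), same length as `z`.
#' @export
predict_f <- function(calibration, z) {
  stopifnot(inherits(calibration, "coassoc_calibration"))
  if (any(abs(z) > calibration$z_range[2] + 1e-9)) {
    coassoc_warn("calibration_range",
      sprintf("|z| = %.3f outside fitted calibration range [%.3f, %.3f]; extrapolating",
              max(abs(z)), calibration$z_range[1], calibration$z_range[2]))
  }
  co <- calibration$coef
  exp(co[["a"]] + co[["b"]] * abs(z) + co[["c"]] * z^2)
}

#' @export
predict.coassoc_calibration <- function(object, z, ...) predict_f(object, z)

#' @export
print.coassoc_calibration <- function(x, ...) {
  cat("Co-association calibration model: f(z) = exp(a + b|z| + c z^2)\n")
  cat(sprintf("  a = %.6f, b = %.6f, c = %.6f\n", x$coef[["a"]], x$coef[["b"]], x$coef[["c"]]))
  cat(sprintf("  fitted on %d grid points, |z| in [%.3f, %.3f], R^2 = %.3f\n",
              nrow(x$grid), x$z_range[1], x$z_range[2], x$r_squared))
  cat(sprintf("  corpus: n_cal = %d, reps_cal = %d, seed = %s, version %s\n",
              x$n_cal, x$reps_cal, format(x$seed), x$version))
  invisible(x)
}

#' Fit a calibration model end to end
#'
#' Convenience wrapper: [empirical_variance_grid()] then [fit_logvar()].
#' The shipped default model uses `n_cal = 10000`, `reps_cal = 500` and a
#' fixed seed; see [default_calibration()].
#'
#' @inheritParams empirical_variance_grid
#' @return A `coassoc_calibration`.
#' @export
calibrate_coassoc <- function(maf_pairs = NULL,
                              r_grid = c(0, 0.15, 0.3, 0.45, 0.6, 0.75, 0.9, 0.95),
                              n_cal = 10000, reps_cal = 500, seed = 1L) {
  fit_logvar(empirical_variance_grid(maf_pairs, r_grid, n_cal, reps_cal, seed))
}

#' The shipped default calibration model
#'
#' Reads (and caches) the plain-text calibration artifact installed with the
#' package, fitted once on the default Gaussian-copula corpus. Use
#' [calibrate_coassoc()] (or the `coassoc calibrate` CLI subcommand) to
#' regenerate it.
#'
#' @return A `coassoc_calibration`.
#' @export
default_calibration <- function() {
  if (is.null(the_coassoc_env$default_cal)) {
    path <- system.file("extdata", "calibration-default.txt", package = "coassoc")
    if (path == "") coassoc_abort("calibration_missing", "shipped calibration artifact not found")
    the_coassoc_env$default_cal <- read_calibration(path)
  }
  the_coassoc_env$default_cal
}

#' Read / write a calibration model as plain text
#'
#' The persistence format is a small `key: value` header (coefficients,
#' corpus settings, seed, package version) followed by the grid as TSV, so
#' the artifact is diffable and survives any text pipeline.
#'
#' @param path File path.
#' @param calibration A `coassoc_calibration` (for writing).
#' @return `read_calibration()` returns a `coassoc_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  split_at <- which(lines == "[grid]")
  hdr <- lines[seq_len(split_at - 1)]
  hdr <- hdr[grepl(":", hdr, fixed = TRUE)]
  kv <- setNames(trimws(sub("^[^:]+:", "", hdr)), trimws(sub(":.*$", "", hdr)))
  grid <- readr::read_tsv(I(lines[(split_at + 1):length(lines)]),
                          show_col_types = FALSE, progress = FALSE)
  new_calibration(
    coef = c(a = as.numeric(kv[["a"]]), b = as.numeric(kv[["b"]]), c = as.numeric(kv[["c"]])),
    grid = grid,
    r_squared = as.numeric(kv[["r_squared"]]),
    sigma = as.numeric(kv[["sigma"]]),
    z_range = c(as.numeric(kv[["z_min"]]), as.numeric(kv[["z_max"]])),
    n_cal = as.integer(kv[["n_cal"]]), reps_cal = as.integer(kv[["reps_cal"]]),
    seed = as.integer(kv[["seed"]])
  )
}

#' @rdname read_calibration
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "coassoc_calibration"))
  hdr <- c(
    "# coassoc calibration model: f(z) = exp(a + b*|z| + c*z^2)",
    sprintf("a: %.17g", calibration$coef[["a"]]),
    sprintf("b: %.17g", calibration$coef[["b"]]),
    sprintf("c: %.17g", calibration$coef[["c"]]),
    sprintf("r_squared: %.17g", calibration$r_squared),
    sprintf("sigma: %.17g", calibration$sigma),
    sprintf("z_min: %.17g", calibration$z_range[1]),
    sprintf("z_max: %.17g", calibration$z_range[2]),
    sprintf("n_cal: %d", calibration$n_cal),
    sprintf("reps_cal: %d", calibration$reps_cal),
    sprintf("seed: %s", format(calibration$seed)),
    sprintf("version: %s", calibration$version),
    "[grid]"
  )
  writeLines(hdr, path)
  readr::write_tsv(calibration$grid, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
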