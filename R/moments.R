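#' Pearson correlation between two genotype vectors
#'
#' Product-moment correlation of two additively coded SNPs (minor-allele
#' counts 0/1/2) within one phenotype group. Degenerate inputs are refused
#' rather than silently propagated: monomorphic SNPs have no defined
#' correlation and perfectly collinear pairs (|r| at the machine boundary of
#' 1) are uninformative duplicates whose Fisher transform diverges.
#'
#' @param x,y Integer or numeric vectors with values in `{0, 1, 2}`, equal
#'   length, at least 4 individuals.
#' @return A single correlation strictly inside (-1, 1); errors otherwise.
#' @examples
#' genotype_cor(c(0, 1, 2, 1, 0, 2, 1, 1), c(1, 0, 2, 1, 0, 2, 0, 1))
#' @export
genotype_cor <- function(x, y) {
  check_genotype_vectors(x, y)
  r <- cor(x, y)
  if (abs(r) > 1 - 1e-8) abort_degenerate_correlation(r)
  r
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`. Under bivariate normality
#' the sampling variance of `z` is approximately `1 / (n - 3)`, which is the
#' reference scale for the calibrated statistic. No clamping is applied:
#' correlations at or beyond the degeneracy threshold `1 - 1e-8` are an error.
#'
#' @param r Correlation(s), each with `|r| < 1 - 1e-8`.
#' @return `atanh(r)`, vectorised.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 - 1e-8)) abort_degenerate_correlation(max(abs(r)))
  atanh(r)
}

#' Central joint moments of a genotype pair
#'
#' Computes the empirical central moments `mu[j,k] = mean((x - mean(x))^j *
#' (y - mean(y))^k)` for all `0 <= j + k <= 4`, the sufficient statistics for
#' the fourth-moment (counting-variable) variance of the sample correlation.
#' Equivalent to summing over the 3x3 genotype contingency table weighted by
#' cell frequencies.
#'
#' @inheritParams genotype_cor
#' @return An object of class `coassoc_moments`: a 5x5 matrix `mu` (rows
#'   `j = 0..4`, columns `k = 0..4`, entries with `j + k > 4` are `NA`) with
#'   attribute `n`.
#' @export
joint_moments <- function(x, y) {
  check_genotype_vectors(x, y)
  dx <- x - mean(x)
  dy <- y - mean(y)
  mu <- matrix(NA_real_, 5, 5, dimnames = list(j = 0:4, k = 0:4))
  for (j in 0:4) for (k in 0:(4 - j)) {
    mu[j + 1, k + 1] <- mean(dx^j * dy^k)
  }
  structure(list(mu = mu, n = length(x)), class = "coassoc_moments")
}

mu_ <- function(m, j, k) m$mu[j + 1, k + 1]

#' @export
print.coassoc_moments <- function(x, ...) {
  cat("Central joint genotype moments (n =", x$n, ")\n")
  print(round(x$mu, 5))
  invisible(x)
}

#' Moment-based variance of the Fisher-z estimate in one group
#'
#' Asymptotic variance of the Fisher-transformed sample correlation for
#' counting variables, via the classical fourth-central-moment delta-method
#' expansion of `Var(r-hat)` mapped to the z scale by the `(1 - r^2)^-2`
#' Jacobian:
#'
#' \deqn{n \,\mathrm{Var}(\hat r) = r^2 \left[\frac{\mu_{40}}{4\mu_{20}^2} +
#'   \frac{\mu_{04}}{4\mu_{02}^2} + \frac{\mu_{22}}{2\mu_{20}\mu_{02}} +
#'   \frac{\mu_{22}}{\mu_{11}^2} - \frac{\mu_{31}}{\mu_{11}\mu_{20}} -
#'   \frac{\mu_{13}}{\mu_{11}\mu_{02}}\right]}
#'
#' For bivariate normal data this reduces to `(1 - r^2)^2 / n`, i.e.
#' `Var(z-hat) ~ 1/n`, recovering Fisher's classical result. When
#' `mu[1,1] ~ 0` (independent SNPs) the bracketed form is numerically
#' unstable and the exact zero-correlation limit
#' `n Var(r-hat) = mu22 / (mu20 mu02)` is used instead.
#'
#' @param m A [joint_moments()] object (or a pair of genotype vectors via
#'   [wz_variance_z_xy()]).
#' @return Estimated `Var(z-hat)` for the group, a positive scalar.
#' @export
wz_variance_z <- function(m) {
  stopifnot(inherits(m, "coassoc_moments"))
  n <- m$n
  if (n < 4L) abort_too_few_samples(n)
  mu20 <- mu_(m, 2, 0); mu02 <- mu_(m, 0, 2); mu11 <- mu_(m, 1, 1)
  if (mu20 <= 0 || mu02 <= 0) abort_zero_variance("a")
  r <- mu11 / sqrt(mu20 * mu02)
  if (abs(r) > 1 - 1e-8) abort_degenerate_correlation(r)
  mu40 <- mu_(m, 4, 0); mu04 <- mu_(m, 0, 4); mu22 <- mu_(m, 2, 2)
  mu31 <- mu_(m, 3, 1); mu13 <- mu_(m, 1, 3)
  # |r| below ~1e-4 loses all precision in the mu11^-1 terms; the limit form
  # is exact at r = 0 and accurate to O(r) nearby.
  if (abs(r) < 1e-4) {
    n_var_r <- mu22 / (mu20 * mu02)
  } else {
    n_var_r <- r^2 * (mu40 / (4 * mu20^2) + mu04 / (4 * mu02^2) +
                      mu22 / (2 * mu20 * mu02) + mu22 / mu11^2 -
                      mu31 / (mu11 * mu20) - mu13 / (mu11 * mu02))
  }
  if (!is.finite(n_var_r) || n_var_r <= 0) {
    coassoc_abort("numerical_instability",
      sprintf("moment-based variance not positive (n*Var(r) = %.4g)", n_var_r))
  }
  (n_var_r / n) / (1 - r^2)^2
}

#' @rdname wz_variance_z
#' @inheritParams genotype_cor
#' @export
wz_variance_z_xy <- function(x, y) wz_variance_z(joint_moments(x, y))
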