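#' Case/control correlation summary for one SNP pair
#'
#' The sufficient statistics shared by the z-difference tests: Pearson
#' correlations of the two SNPs among cases, among controls, and pooled,
#' with their Fisher transforms and the group sizes.
#'
#' @param g1_case,g2_case Genotypes (0/1/2) of SNP1 and SNP2 among cases.
#' @param g1_ctrl,g2_ctrl Genotypes of the same SNPs among controls.
#' @return A one-row tibble with columns `r_case`, `r_ctrl`, `r_pooled`,
#'   `z_case`, `z_ctrl`, `z_pooled`, `n_case`, `n_ctrl`.
#' @export
pair_correlation <- function(g1_case, g2_case, g1_ctrl, g2_ctrl) {
  check_genotype_vectors(g1_case, g2_case, "case")
  check_genotype_vectors(g1_ctrl, g2_ctrl, "control")
  r_case <- cor(g1_case, g2_case)
  r_ctrl <- cor(g1_ctrl, g2_ctrl)
  r_pooled <- cor(c(g1_case, g1_ctrl), c(g2_case, g2_ctrl))
  for (r in c(r_case, r_ctrl, r_pooled)) {
    if (abs(r) > 1 - 1e-8) abort_degenerate_correlation(r)
  }
  tibble(
    r_case = r_case, r_ctrl = r_ctrl, r_pooled = r_pooled,
    z_case = atanh(r_case), z_ctrl = atanh(r_ctrl), z_pooled = atanh(r_pooled),
    n_case = length(g1_case), n_ctrl = length(g1_ctrl)
  )
}

# two-sided normal p-value
p_two_sided <- function(stat) 2 * pnorm(-abs(stat))

#' Plain Fisher z-difference test between case and control correlations
#'
#' Fisher's classical two-sample comparison of correlation coefficients,
#' applied to the case/control genotype correlations of a SNP pair:
#' `stat = (z_case - z_ctrl) / sqrt(1/(n_case - 3) + 1/(n_ctrl - 3))`,
#' referred to the standard normal (two-sided). Exact under bivariate
#' normality; for genotype counts its null variance drifts from 1 as the
#' correlation grows, which the moment-based and calibrated variants repair.
#'
#' @param z_case,z_ctrl Fisher-transformed group correlations.
#' @param n_case,n_ctrl Group sizes (each > 3).
#' @return A list with elements `stat` and `p`.
#' @export
fisher_cor_test <- function(z_case, z_ctrl, n_case, n_ctrl) {
  if (n_case <= 3 || n_ctrl <= 3) abort_too_few_samples(min(n_case, n_ctrl))
  stat <- (z_case - z_ctrl) / sqrt(1 / (n_case - 3) + 1 / (n_ctrl - 3))
  list(stat = stat, p = p_two_sided(stat))
}

#' Moment-variance co-association test
#'
#' The z-difference statistic with a per-group variance from the
#' fourth-moment asymptotic distribution of the sample correlation for
#' counting variables ([wz_variance_z()]):
#' `stat = (z_case - z_ctrl) / sqrt(V_case + V_ctrl)`.
#' The variance is evaluated separately in cases and in controls, the only
#' form consistent with a null hypothesis of equal (but arbitrary)
#' correlations in the two groups.
#'
#' @inheritParams pair_correlation
#' @return A list with `stat`, `p`, `var_case`, `var_ctrl`.
#' @export
wz_cor_test <- function(g1_case, g2_case, g1_ctrl, g2_ctrl) {
  v_case <- with_group_tag(wz_variance_z_xy(g1_case, g2_case), "case")
  v_ctrl <- with_group_tag(wz_variance_z_xy(g1_ctrl, g2_ctrl), "control")
  z_case <- fisher_z(cor(g1_case, g2_case))
  z_ctrl <- fisher_z(cor(g1_ctrl, g2_ctrl))
  stat <- (z_case - z_ctrl) / sqrt(v_case + v_ctrl)
  list(stat = stat, p = p_two_sided(stat), var_case = v_case, var_ctrl = v_ctrl)
}

# re-raise a group-level failure with the group recorded
with_group_tag <- function(expr, group) {
  withCallingHandlers(expr, coassoc_error = function(e) {
    if (is.null(e$group) || e$group == "a") {
      cls <- setdiff(class(e), c("error", "condition"))
      rlang::abort(sub("\\ba group\\b", paste(group, "group"), conditionMessage(e)),
                   class = cls, group = group)
    }
  })
}

#' Calibrated fast co-association test
#'
#' The plain Fisher z-difference with its `1/(n-3)` variance inflated by an
#' empirically calibrated multiplier `f(z_pooled)` that absorbs the
#' departure of genotype counts from bivariate normality at high
#' correlation:
#' `stat = (z_case - z_ctrl) / sqrt(f(z_pooled) * (1/(n_case-3) + 1/(n_ctrl-3)))`.
#' Needs only the three correlations and the group sizes, so it is the
#' statistic of choice for exhaustive pairwise scans.
#'
#' @param pc A [pair_correlation()] row (or anything with the same fields).
#' @param calibration A calibration model fitted by [calibrate_coassoc()];
#'   defaults to the shipped model ([default_calibration()]).
#' @return A list with `stat`, `p`, `f` (the multiplier used).
#' @export
calib_cor_test <- function(pc, calibration = default_calibration()) {
  f <- predict_f(calibration, pc$z_pooled)
  denom <- sqrt(f * (1 / (pc$n_case - 3) + 1 / (pc$n_ctrl - 3)))
  stat <- (pc$z_case - pc$z_ctrl) / denom
  list(stat = stat, p = p_two_sided(stat), f = f)
}

#' Logistic-regression interaction test (product term)
#'
#' The classical comparator: fits
#' `logit P(D = 1) = b0 + b1 g1 + b2 g2 + b3 g1 g2`
#' by iteratively reweighted least squares on the pooled sample and tests
#' `b3 = 0` with the 1-df likelihood-ratio statistic (Wald optionally).
#'
#' @param g1,g2 Genotype vectors (0/1/2) over the pooled sample.
#' @param phenotype Binary 0/1 disease status, aligned with `g1`/`g2`;
#'   both classes must be present.
#' @param wald Also return the Wald z statistic for the product term.
#' @param max_iter,tol IRLS iteration cap and deviance convergence tolerance.
#' @return A list with `stat` (1-df chi-square), `p`, `coef` (length 4), and
#'   if `wald = TRUE` also `wald_stat`, `wald_p`.
#' @export
lrt_interaction <- function(g1, g2, phenotype, wald = FALSE,
                            max_iter = 100L, tol = 1e-8) {
  n <- length(phenotype)
  if (length(g1) != n || length(g2) != n) abort_length_mismatch(length(g1), n)
  if (!all(phenotype %in% c(0, 1)) || length(unique(phenotype)) < 2L) {
    coassoc_abort("phenotype_error", "phenotype must be binary 0/1 with both classes present")
  }
  ctl <- glm.control(epsilon = tol, maxit = max_iter)
  x_full <- cbind(`(Intercept)` = 1, g1 = g1, g2 = g2, `g1:g2` = g1 * g2)
  fit1 <- glm.fit(x_full, phenotype, family = binomial(), control = ctl)
  fit0 <- glm.fit(x_full[, 1:3, drop = FALSE], phenotype, family = binomial(), control = ctl)
  # separation: runaway coefficients, or fitted probabilities pinned at the
  # boundary (IRLS can meet the deviance tolerance at the boundary with
  # finite coefficients, so the norm check alone is not sufficient)
  pinned <- any(fit1$fitted.values < 1e-10 | fit1$fitted.values > 1 - 1e-10)
  if (any(abs(fit1$coefficients) > 1e3, na.rm = TRUE) || pinned) {
    coassoc_abort("separation", "perfect separation detected in logistic interaction fit")
  }
  if (!fit1$converged || !fit0$converged) {
    coassoc_abort("convergence", sprintf("IRLS did not converge in %d iterations", max_iter))
  }
  stat <- max(0, fit0$deviance - fit1$deviance)
  out <- list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
              coef = fit1$coefficients)
  if (wald) {
    # observed-information SE from the weighted cross-product at convergence
    w <- fit1$weights
    xtwx <- crossprod(x_full * sqrt(w))
    se <- sqrt(diag(solve(xtwx)))[4]
    out$wald_stat <- fit1$coefficients[4] / se
    out$wald_p <- p_two_sided(out$wald_stat)
  }
  out
}

minor_allele_freq <- function(g) {
  p <- mean(g) / 2
  min(p, 1 - p)
}

#' Test one SNP pair for gene-gene co-association
#'
#' Runs the selected co-association statistics on a single SNP pair held in
#' a data frame of individuals: the plain Fisher z-difference (`"fisher"`),
#' the moment-variance test (`"wz"`), the calibrated fast test (`"calib"`)
#' and the logistic interaction comparator (`"lrt"`). Individuals missing
#' either genotype are dropped (pairwise complete case, per group). SNPs
#' with within-dataset minor allele frequency below `maf_min` are refused:
#' the z-difference tests are unreliable for rare variation.
#'
#' @param data A data frame with one row per individual.
#' @param snp1,snp2 Columns (tidy-eval) holding minor-allele counts 0/1/2.
#' @param phenotype Column holding binary 0/1 case status.
#' @param stats Character subset of `c("fisher", "wz", "calib", "lrt")`.
#' @param calibration Calibration model for the `"calib"` statistic.
#' @param maf_min Minimum within-dataset minor allele frequency (default 0.05).
#' @param allow_rare Run anyway below `maf_min`, with a warning.
#' @return A one-row tibble: pair correlations and sizes, plus `stat_*` /
#'   `p_*` columns for each selected statistic. Swapping case and control
#'   labels negates the three z-statistics and leaves every p-value
#'   unchanged.
#' @examples
#' set.seed(1)
#' d <- simulate_scenario(coassoc_scenario(beta3 = 0.3, n_sample = 800))
#' coassoc_test(d, snp1, snp2, phenotype)
#' @export
coassoc_test <- function(data, snp1, snp2, phenotype,
                         stats = c("fisher", "wz", "calib", "lrt"),
                         calibration = default_calibration(),
                         maf_min = 0.05, allow_rare = FALSE) {
  stats <- match.arg(stats, c("fisher", "wz", "calib", "lrt"), several.ok = TRUE)
  g1 <- dplyr::pull(data, {{ snp1 }})
  g2 <- dplyr::pull(data, {{ snp2 }})
  ph <- dplyr::pull(data, {{ phenotype }})
  keep <- complete.cases(g1, g2, ph)
  g1 <- g1[keep]; g2 <- g2[keep]; ph <- ph[keep]
  if (!all(ph %in% c(0, 1))) {
    coassoc_abort("phenotype_error", "phenotype must be binary 0/1")
  }
  for (g in list(g1, g2)) {
    m <- minor_allele_freq(g)
    if (m < maf_min) {
      if (allow_rare) {
        coassoc_warn("rare_variant",
          sprintf("MAF %.4f below maf_min = %.3f; z-difference tests are unreliable for rare variants", m, maf_min))
      } else {
        coassoc_abort("rare_variant",
          sprintf("MAF %.4f below maf_min = %.3f (set allow_rare = TRUE to override)", m, maf_min))
      }
    }
  }
  coassoc_pair_test(g1[ph == 1], g2[ph == 1], g1[ph == 0], g2[ph == 0],
                    g1_pooled = g1, g2_pooled = g2, phenotype = ph,
                    stats = stats, calibration = calibration)
}

#' @rdname coassoc_test
#' @inheritParams pair_correlation
#' @param g1_pooled,g2_pooled Pooled genotype vectors for the LRT (defaults
#'   to concatenating cases then controls).
#' @export
coassoc_pair_test <- function(g1_case, g2_case, g1_ctrl, g2_ctrl,
                              stats = c("fisher", "wz", "calib", "lrt"),
                              calibration = default_calibration(),
                              g1_pooled = c(g1_case, g1_ctrl),
                              g2_pooled = c(g2_case, g2_ctrl),
                              phenotype = rep(c(1, 0), c(length(g1_case), length(g1_ctrl)))) {
  stats <- match.arg(stats, c("fisher", "wz", "calib", "lrt"), several.ok = TRUE)
  pc <- pair_correlation(g1_case, g2_case, g1_ctrl, g2_ctrl)
  out <- pc
  if ("fisher" %in% stats) {
    ft <- fisher_cor_test(pc$z_case, pc$z_ctrl, pc$n_case, pc$n_ctrl)
    out$stat_fisher <- ft$stat; out$p_fisher <- ft$p
  }
  if ("wz" %in% stats) {
    wt <- wz_cor_test(g1_case, g2_case, g1_ctrl, g2_ctrl)
    out$stat_wz <- wt$stat; out$p_wz <- wt$p
  }
  if ("calib" %in% stats) {
    ct <- calib_cor_test(pc, calibration)
    out$stat_calib <- ct$stat; out$p_calib <- ct$p
  }
  if ("lrt" %in% stats) {
    lt <- lrt_interaction(g1_pooled, g2_pooled, phenotype)
    out$stat_lrt <- lt$stat; out$p_lrt <- lt$p
  }
  out
}
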