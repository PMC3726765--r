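# Gaussian-copula genotype simulator.
#
# A biallelic SNP with minor allele frequency p has Hardy-Weinberg genotype
# probabilities ((1-p)^2, 2p(1-p), p^2). A latent standard normal is cut at
# the matching quantiles; a pair of SNPs shares a latent bivariate normal
# whose correlation is solved numerically so the induced genotype-scale
# Pearson correlation equals the requested target. This reproduces the two
# features real LD-driven pipelines provide — HWE margins and a controllable
# inter-SNP correlation — with no external haplotype data.

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

genotype_cutpoints <- function(maf) qnorm(cumsum(hwe_probs(maf))[1:2])

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
# by one-dimensional integration of the conditional normal CDF.
bvn_upper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a, lower.tail = FALSE) * pnorm(b, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) * pnorm((b - rho * z) / s, lower.tail = FALSE),
            lower = a, upper = Inf, rel.tol = 1e-10)$value
}

# 3x3 joint genotype cell probabilities under the copula.
copula_cell_probs <- function(maf1, maf2, rho) {
  t1 <- c(-Inf, genotype_cutpoints(maf1), Inf)
  t2 <- c(-Inf, genotype_cutpoints(maf2), Inf)
  up <- matrix(0, 4, 4)
  for (j in 1:4) for (k in 1:4) up[j, k] <- bvn_upper(t1[j], t2[k], rho)
  cells <- matrix(0, 3, 3, dimnames = list(g1 = 0:2, g2 = 0:2))
  for (j in 1:3) for (k in 1:3) {
    cells[j, k] <- up[j, k] - up[j + 1, k] - up[j, k + 1] + up[j + 1, k + 1]
  }
  pmax(cells, 0)
}

# Genotype-scale Pearson correlation induced by latent correlation rho.
copula_genotype_cor <- function(rho, maf1, maf2) {
  t1 <- genotype_cutpoints(maf1)
  t2 <- genotype_cutpoints(maf2)
  # E[G1 G2] = sum_{j,k in {1,2}} P(G1 >= j, G2 >= k) for counts in {0,1,2}
  e12 <- 0
  for (j in 1:2) for (k in 1:2) e12 <- e12 + bvn_upper(t1[j], t2[k], rho)
  m1 <- 2 * maf1; m2 <- 2 * maf2
  v1 <- 2 * maf1 * (1 - maf1); v2 <- 2 * maf2 * (1 - maf2)
  (e12 - m1 * m2) / sqrt(v1 * v2)
}

#' Attainable genotype correlation interval for a MAF pair
#'
#' The Gaussian-copula construction cannot reach every correlation: the
#' bounds are the genotype-scale correlations induced by latent correlation
#' at (minus/plus) `1 - 1e-6`, i.e. the (anti)comonotone coupling of the two
#' HWE margins.
#'
#' @param maf1,maf2 Minor allele frequencies in (0, 0.5].
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
feasible_cor_range <- function(maf1, maf2) {
  c(copula_genotype_cor(-(1 - 1e-6), maf1, maf2),
    copula_genotype_cor(1 - 1e-6, maf1, maf2))
}

# Invert r(rho) = r_target by uniroot; r(rho) is strictly increasing.
solve_latent_rho <- function(r_target, maf1, maf2) {
  if (r_target == 0) return(0)
  bounds <- feasible_cor_range(maf1, maf2)
  if (r_target <= bounds[1] || r_target >= bounds[2]) {
    abort_infeasible_correlation(r_target, bounds)
  }
  uniroot(function(rho) copula_genotype_cor(rho, maf1, maf2) - r_target,
          lower = -(1 - 1e-6), upper = 1 - 1e-6, tol = 1e-9)$root
}

cut_latent <- function(z, maf) {
  t <- genotype_cutpoints(maf)
  (z >= t[1]) + (z >= t[2])
}

#' Simulate a correlated pair of SNP genotype vectors
#'
#' Draws `n` individuals whose two SNPs are marginally binomial(2, maf)
#' (Hardy-Weinberg) and whose genotype-scale Pearson correlation converges
#' to `r_target`, via a thresholded latent bivariate normal.
#'
#' @param n Number of individuals.
#' @param maf1,maf2 Minor allele frequencies in (0, 0.5].
#' @param r_target Target genotype-scale Pearson correlation; must lie in
#'   [feasible_cor_range()] for this MAF pair.
#' @param seed Optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param latent_rho Pre-solved latent correlation (skips the numeric
#'   inversion; used internally by scenario objects).
#' @return A tibble with integer columns `snp1`, `snp2`.
#' @export
simulate_genotype_pair <- function(n, maf1, maf2, r_target = 0, seed = NULL,
                                   latent_rho = NULL) {
  if (is.null(latent_rho)) latent_rho <- solve_latent_rho(r_target, maf1, maf2)
  draw <- function() {
    z1 <- rnorm(n)
    z2 <- latent_rho * z1 + sqrt(1 - latent_rho^2) * rnorm(n)
    tibble(snp1 = cut_latent(z1, maf1), snp2 = cut_latent(z2, maf2))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate an LD block of SNPs with AR(1) latent correlation
#'
#' `m = length(mafs)` SNPs share a latent AR(1) Gaussian process with
#' parameter `rho`, so the latent correlation between SNPs `i` and `j` is
#' `rho^|i-j|` and genotype-scale LD decays monotonically with distance.
#' Each margin is Hardy-Weinberg at its own MAF.
#'
#' @param n Number of individuals.
#' @param mafs Vector of minor allele frequencies, one per SNP.
#' @param rho Latent AR(1) correlation in (-1, 1).
#' @param seed Optional integer seed.
#' @return A tibble with columns `snp_1 ... snp_m` (0/1/2).
#' @export
simulate_ld_block <- function(n, mafs, rho, seed = NULL) {
  stopifnot(abs(rho) < 1, length(mafs) >= 1)
  draw <- function() {
    m <- length(mafs)
    z <- matrix(0, n, m)
    z[, 1] <- rnorm(n)
    if (m > 1) {
      s <- sqrt(1 - rho^2)
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * rnorm(n)
    }
    g <- vapply(seq_len(m), function(j) cut_latent(z[, j], mafs[j]), numeric(n))
    colnames(g) <- paste0("snp_", seq_len(m))
    as_tibble(g)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a two-block LD region with a shared regional factor
#'
#' Two adjacent haplotype blocks (e.g. two neighbouring genes) whose SNPs
#' share one regional latent factor plus block-wise AR(1) noise:
#' the latent correlation is `cross + (1 - cross) * rho^|i-j|` within a
#' block and `cross` between blocks. With the defaults (`rho = 0.9`,
#' `cross = 0.5`) adjacent within-block SNPs sit near latent 0.95 and
#' between-block pairs near 0.5, the structure of a strong-LD region with
#' two linked genes.
#'
#' @param n Number of individuals.
#' @param mafs Minor allele frequencies, one per SNP.
#' @param blocks Integer block label per SNP (same length as `mafs`).
#' @param rho Within-block AR(1) parameter.
#' @param cross Shared-factor variance fraction = between-block latent
#'   correlation, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A tibble `snp_1 ... snp_m` (0/1/2) with attribute `blocks`.
#' @export
simulate_ld_region <- function(n, mafs, blocks, rho = 0.9, cross = 0.5,
                               seed = NULL) {
  stopifnot(length(blocks) == length(mafs), abs(rho) < 1, cross >= 0, cross < 1)
  draw <- function() {
    m <- length(mafs)
    f <- rnorm(n)
    z <- matrix(0, n, m)
    s <- sqrt(1 - rho^2)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      e <- matrix(0, n, length(idx))
      e[, 1] <- rnorm(n)
      if (length(idx) > 1) {
        for (j in 2:length(idx)) e[, j] <- rho * e[, j - 1] + s * rnorm(n)
      }
      z[, idx] <- sqrt(cross) * f + sqrt(1 - cross) * e
    }
    g <- vapply(seq_len(m), function(j) cut_latent(z[, j], mafs[j]), numeric(n))
    colnames(g) <- paste0("snp_", seq_len(m))
    out <- as_tibble(g)
    attr(out, "blocks") <- blocks
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Assign case-control status from a two-SNP logistic disease model
#'
#' Each individual is a Bernoulli draw with
#' `P(D = 1) = plogis(beta0 + beta1 g1 + beta2 g2 + beta3 g1 g2)`.
#'
#' @param g1,g2 Aligned genotype vectors (0/1/2).
#' @param beta0,beta1,beta2,beta3 Logistic coefficients on the log-odds
#'   scale; `beta3` is the product (interaction) term.
#' @param seed Optional integer seed.
#' @return Integer 0/1 phenotype vector.
#' @export
assign_phenotype <- function(g1, g2, beta0, beta1 = 0, beta2 = 0, beta3 = 0,
                             seed = NULL) {
  if (length(g1) != length(g2)) abort_length_mismatch(length(g1), length(g2))
  p <- plogis(beta0 + beta1 * g1 + beta2 * g2 + beta3 * g1 * g2)
  draw <- function() rbinom(length(g1), 1L, p)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Intercept giving a target population prevalence
#'
#' Solves `E[plogis(beta0 + beta1 G1 + beta2 G2 + beta3 G1 G2)] = prevalence`
#' over the joint copula genotype distribution by root finding on the 3x3
#' cell mixture.
#'
#' @inheritParams simulate_genotype_pair
#' @param beta1,beta2,beta3 Disease-model coefficients.
#' @param prevalence Target population disease probability (default 0.5).
#' @return The intercept `beta0`.
#' @export
solve_beta0 <- function(maf1, maf2, r_target = 0, beta1 = 0, beta2 = 0,
                        beta3 = 0, prevalence = 0.5) {
  rho <- solve_latent_rho(r_target, maf1, maf2)
  cells <- copula_cell_probs(maf1, maf2, rho)
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  w <- as.vector(cells)
  prev <- function(b0) {
    sum(w * plogis(b0 + beta1 * g$g1 + beta2 * g$g2 + beta3 * g$g1 * g$g2)) - prevalence
  }
  uniroot(prev, lower = -25, upper = 25, tol = 1e-10)$root
}

#' Define one simulation condition (scenario)
#'
#' Bundles the generative parameters of a two-SNP case-control study: MAFs,
#' inter-SNP genotype correlation, logistic disease-model coefficients,
#' sample and population sizes, replicate count and seed. The latent copula
#' correlation and (when `beta0 = NULL`) the prevalence-matching intercept
#' are resolved once at construction.
#'
#' The co-association taxonomy label is derived from the parameters:
#' interaction with independent SNPs (`"I"`), correlation with main effects
#' but no interaction (`"II"`), both (`"III"`), otherwise `"null"` (no
#' interaction and either no correlation or no main effects).
#'
#' @param maf1,maf2 Minor allele frequencies (defaults 0.20 and 0.30, the
#'   canonical simulation margins).
#' @param r Target genotype-scale correlation between the two SNPs.
#' @param beta1,beta2,beta3 Logistic coefficients; see [assign_phenotype()].
#' @param main_effects Convenience shortcut: `"none"`, `"one"` or `"two"`
#'   sets `beta1`/`beta2` to `log(1.3)` accordingly (odds ratio 1.3 per
#'   allele). Ignored when `NULL`.
#' @param beta0 Intercept; `NULL` solves for `prevalence`.
#' @param prevalence Target population prevalence used when `beta0 = NULL`.
#' @param n_sample Individuals drawn per replicate study.
#' @param n_population Population generated before sampling (the sample is
#'   drawn without replacement, irrespective of status).
#' @param reps Replicate count for experiment drivers.
#' @param seed Optional base seed.
#' @return A `coassoc_scenario` object (list).
#' @export
coassoc_scenario <- function(maf1 = 0.2, maf2 = 0.3, r = 0,
                             beta1 = 0, beta2 = 0, beta3 = 0,
                             main_effects = NULL,
                             beta0 = NULL, prevalence = 0.5,
                             n_sample = 3000, n_population = 2 * n_sample,
                             reps = 3000, seed = NULL) {
  if (!is.null(main_effects)) {
    main_effects <- match.arg(main_effects, c("none", "one", "two"))
    beta1 <- if (main_effects == "none") 0 else log(1.3)
    beta2 <- if (main_effects == "two") log(1.3) else 0
  }
  stopifnot(n_population >= n_sample)
  latent_rho <- solve_latent_rho(r, maf1, maf2)
  if (is.null(beta0)) {
    beta0 <- solve_beta0(maf1, maf2, r, beta1, beta2, beta3, prevalence)
  }
  has_main <- beta1 != 0 || beta2 != 0
  type <- if (beta3 != 0 && r == 0) "I"
          else if (beta3 == 0 && r != 0 && has_main) "II"
          else if (beta3 != 0 && r != 0) "III"
          else "null"
  structure(list(
    maf1 = maf1, maf2 = maf2, r = r, latent_rho = latent_rho,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
    n_sample = n_sample, n_population = n_population,
    reps = reps, seed = seed, coassoc_type = type
  ), class = "coassoc_scenario")
}

#' @export
print.coassoc_scenario <- function(x, ...) {
  cat(sprintf("Co-association scenario (type %s)\n", x$coassoc_type))
  cat(sprintf("  MAFs %.2f / %.2f, genotype r = %.2f (latent rho = %.4f)\n",
              x$maf1, x$maf2, x$r, x$latent_rho))
  cat(sprintf("  logit P(D) = %.3f + %.3f g1 + %.3f g2 + %.3f g1*g2\n",
              x$beta0, x$beta1, x$beta2, x$beta3))
  cat(sprintf("  n_sample %d of population %d, %d replicates\n",
              x$n_sample, x$n_population, x$reps))
  invisible(x)
}

#' Draw one case-control study from a scenario
#'
#' Generates a population of `n_population` individuals (correlated SNP pair
#' plus logistic phenotype), then samples `n_sample` of them uniformly
#' without replacement — irrespective of status, mirroring a
#' population-based study. A draw with fewer than 50 cases or 50 controls is
#' rejected and redrawn (at most 10 attempts, with a warning).
#'
#' @param scenario A [coassoc_scenario()].
#' @param seed Optional integer seed overriding `scenario$seed`.
#' @return A tibble with columns `snp1`, `snp2`, `phenotype` and attributes
#'   `scenario` and `achieved` (realised MAFs and correlation).
#' @export
draw_study <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "coassoc_scenario"))
  if (is.null(seed)) seed <- scenario$seed
  draw <- function() {
    for (attempt in 1:10) {
      pop <- simulate_genotype_pair(scenario$n_population, scenario$maf1,
                                    scenario$maf2, latent_rho = scenario$latent_rho)
      pop$phenotype <- assign_phenotype(pop$snp1, pop$snp2, scenario$beta0,
                                        scenario$beta1, scenario$beta2,
                                        scenario$beta3)
      idx <- sample.int(scenario$n_population, scenario$n_sample)
      smp <- pop[idx, ]
      n_case <- sum(smp$phenotype)
      if (n_case >= 50 && scenario$n_sample - n_case >= 50) {
        attr(smp, "scenario") <- scenario
        attr(smp, "achieved") <- c(maf1 = mean(smp$snp1) / 2,
                                   maf2 = mean(smp$snp2) / 2,
                                   r = cor(smp$snp1, smp$snp2))
        return(smp)
      }
      coassoc_warn("degenerate_study",
        sprintf("drawn sample had %d cases; redrawing (attempt %d/10)", n_case, attempt))
    }
    coassoc_abort("degenerate_study",
      "could not draw a sample with at least 50 cases and 50 controls in 10 attempts")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @rdname draw_study
#' @export
simulate_scenario <- function(scenario, seed = NULL) draw_study(scenario, seed)

#' Embed a causal SNP block into a background genotype matrix
#'
#' Column-concatenates a block of (typically causal, correlated) SNPs onto a
#' background panel of null SNPs over the same individuals, recording which
#' columns are causal — the "gain-of-function" construction used by the
#' multi-cohort false-positive study.
#'
#' @param background,block Data frames / tibbles of genotypes with equal row
#'   counts (individuals).
#' @return A tibble with all columns and attribute `causal` (logical vector
#'   marking the block's columns).
#' @export
embed_causal_block <- function(background, block) {
  if (ncol(block) == 0) {
    out <- as_tibble(background)
    attr(out, "causal") <- rep(FALSE, ncol(background))
    return(out)
  }
  if (nrow(background) != nrow(block)) {
    coassoc_abort("row_mismatch",
      sprintf("background has %d rows, block has %d", nrow(background), nrow(block)))
  }
  out <- dplyr::bind_cols(as_tibble(background), as_tibble(block),
                          .name_repair = "minimal")
  attr(out, "causal") <- c(rep(FALSE, ncol(background)), rep(TRUE, ncol(block)))
  out
}
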