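# Scripted simulation experiments: type-I error tables, power curves,
# LD robustness, and the multi-cohort false-positive study. Every driver is
# deterministic given its seed and reports Monte-Carlo standard errors.

#' Rejection rates for one scenario
#'
#' The replicate engine behind every experiment: draws `reps` studies from a
#' scenario, runs the selected statistics on the causal SNP pair, and
#' summarises per-statistic rejection rates at `alpha` with their binomial
#' Monte-Carlo standard errors. Replicates where a statistic is untestable
#' (monomorphic draw, degenerate correlation) are excluded from that
#' statistic's denominator; the count is reported.
#'
#' @param scenario A [coassoc_scenario()].
#' @param stats Statistics to run.
#' @param reps Replicates (defaults to `scenario$reps`).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed (defaults to `scenario$seed`).
#' @param calibration Calibration model for `"calib"`.
#' @return A tibble: `statistic`, `rate`, `mc_se`, `n_reps`, `n_skipped`,
#'   plus the scenario descriptors (`maf1 maf2 r beta1 beta2 beta3
#'   n_sample alpha seed`).
#' @export
reject_rates <- function(scenario, stats = c("fisher", "wz", "calib", "lrt"),
                         reps = scenario$reps, alpha = 0.05,
                         seed = scenario$seed,
                         calibration = default_calibration()) {
  stats <- match.arg(stats, c("fisher", "wz", "calib", "lrt"), several.ok = TRUE)
  force(calibration)
  pv <- matrix(NA_real_, reps, length(stats), dimnames = list(NULL, stats))
  run <- function() {
    for (i in seq_len(reps)) {
      smp <- draw_study(scenario)
      case <- smp$phenotype == 1
      rec <- pair_record(smp$snp1[case], smp$snp2[case],
                         smp$snp1[!case], smp$snp2[!case],
                         stats, calibration,
                         g1 = smp$snp1, g2 = smp$snp2, ph = smp$phenotype)
      for (s in stats) pv[i, s] <<- rec[[paste0("p_", s)]]
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
  purrr::map_dfr(stats, function(s) {
    p <- pv[, s]
    ok <- !is.na(p)
    rate <- mean(p[ok] < alpha)
    tibble(statistic = s, rate = rate,
           mc_se = sqrt(rate * (1 - rate) / sum(ok)),
           n_reps = sum(ok), n_skipped = sum(!ok),
           maf1 = scenario$maf1, maf2 = scenario$maf2, r = scenario$r,
           beta1 = scenario$beta1, beta2 = scenario$beta2,
           beta3 = scenario$beta3, n_sample = scenario$n_sample,
           alpha = alpha, seed = seed %||% NA_integer_)
  })
}

#' Type-I error tables under the two null designs
#'
#' `type1_main_effects()` is the uncorrelated-null table: independent SNPs
#' (zero correlation), no interaction, one or two main effects (log odds ratio
#' `log(1.3)` per allele), across sample sizes. `type1_correlation()` is the
#' correlated-null table: no main effects, no interaction, correlation
#' swept over `r_grid` at each sample size. `type1_tables()` runs both.
#'
#' @param reps Replicates per cell (3000 reproduces the reference tables;
#'   use fewer for smoke runs — a warning is emitted below 3000).
#' @param n_grid Sample sizes per replicate.
#' @param main_effects Which main-effect settings to include.
#' @param r_grid Correlations for the correlated-null table.
#' @param stats Statistics to evaluate.
#' @param alpha Nominal level.
#' @param seed Base seed; each cell derives its own sub-seed deterministically.
#' @param calibration Calibration model.
#' @return A tibble of class `coassoc_experiment` in long format: one row
#'   per (cell, statistic) with `rate` and `mc_se`.
#' @export
type1_main_effects <- function(reps = 3000, n_grid = c(1000, 2000, 3000, 4000, 5000),
                               main_effects = c("one", "two"),
                               stats = c("fisher", "wz", "calib", "lrt"),
                               alpha = 0.05, seed = 1L,
                               calibration = default_calibration()) {
  check_reps(reps)
  cells <- tidyr::expand_grid(n_sample = n_grid, main_effects = main_effects)
  out <- purrr::pmap(cells, function(n_sample, main_effects) {
    sc <- coassoc_scenario(main_effects = main_effects, r = 0, beta3 = 0,
                           n_sample = n_sample, reps = reps)
    res <- reject_rates(sc, stats, reps, alpha, seed = cell_seed(seed, n_sample, main_effects),
                        calibration = calibration)
    res$main_effects <- main_effects
    res
  })
  as_experiment(dplyr::bind_rows(out), "type1_main_effects")
}

#' @rdname type1_main_effects
#' @param maf1,maf2 Primary MAF pair (defaults 0.20/0.30).
#' @param maf_fallback MAF pair used for correlations beyond the attainable
#'   (Frechet) bound of the primary pair. HWE margins at MAF 0.2/0.3 cap
#'   the genotype correlation at about 0.79 for *any* joint distribution,
#'   so the correlation-0.8 row is simulated at equal MAFs 0.3/0.3 by
#'   default.
#' @export
type1_correlation <- function(reps = 3000, r_grid = c(0.2, 0.4, 0.6, 0.8),
                              n_grid = c(3000, 5000),
                              maf1 = 0.2, maf2 = 0.3,
                              maf_fallback = c(0.3, 0.3),
                              stats = c("fisher", "wz", "calib", "lrt"),
                              alpha = 0.05, seed = 1L,
                              calibration = default_calibration()) {
  check_reps(reps)
  cells <- tidyr::expand_grid(r = r_grid, n_sample = n_grid)
  out <- purrr::pmap(cells, function(r, n_sample) {
    m <- pick_feasible_mafs(r, maf1, maf2, maf_fallback)
    sc <- coassoc_scenario(maf1 = m[1], maf2 = m[2], main_effects = "none",
                           r = r, beta3 = 0, n_sample = n_sample, reps = reps)
    reject_rates(sc, stats, reps, alpha, seed = cell_seed(seed, n_sample, r),
                 calibration = calibration)
  })
  as_experiment(dplyr::bind_rows(out), "type1_correlation")
}

# keep the primary MAF pair when the target correlation is attainable with a
# small safety margin; otherwise switch to the fallback pair
pick_feasible_mafs <- function(r, maf1, maf2, fallback = c(0.3, 0.3)) {
  bounds <- feasible_cor_range(maf1, maf2)
  if (r > bounds[1] + 0.005 && r < bounds[2] - 0.005) return(c(maf1, maf2))
  rlang::inform(sprintf(
    "r = %g outside the attainable interval [%.3f, %.3f] for MAFs %.2f/%.2f; using fallback MAFs %.2f/%.2f",
    r, bounds[1], bounds[2], maf1, maf2, fallback[1], fallback[2]))
  fallback
}

#' @rdname type1_main_effects
#' @export
type1_tables <- function(reps = 3000, n_grid = c(1000, 2000, 3000, 4000, 5000),
                         r_grid = c(0.2, 0.4, 0.6, 0.8),
                         stats = c("fisher", "wz", "calib", "lrt"),
                         alpha = 0.05, seed = 1L,
                         calibration = default_calibration()) {
  list(main_effects = type1_main_effects(reps, n_grid, stats = stats,
                                         alpha = alpha, seed = seed,
                                         calibration = calibration),
       correlation = type1_correlation(reps, r_grid, stats = stats,
                                       alpha = alpha, seed = seed,
                                       calibration = calibration))
}

check_reps <- function(reps) {
  stopifnot(reps >= 100)
  if (reps < 3000) {
    rlang::inform(sprintf(
      "reps = %d below the reference 3000; Monte-Carlo error ~ %.3f at rate 0.05",
      reps, sqrt(0.05 * 0.95 / reps)))
  }
  invisible(reps)
}

# deterministic sub-seed per experiment cell, kept under 2^31
cell_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "|")
  as.integer(sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)) %% 2147483587L) + seed
}

as_experiment <- function(x, which) {
  class(x) <- c("coassoc_experiment", class(x))
  attr(x, "experiment") <- which
  x
}

#' Power curves across the co-association taxonomy
#'
#' Four panels: (a) interaction only — independent SNPs, `beta3` swept;
#' (b) correlation only — `beta3 = 0`, `r` swept (with main effects, this
#' is where the interaction LRT loses power while the z-difference tests do
#' not); (c) both, interaction fixed at 0.2, `r` swept; (d) both, `r` fixed
#' at 0.4, `beta3` swept. Each panel is crossed with no/one/two main
#' effects.
#'
#' @param panels Subset of `c("a", "b", "c", "d")`.
#' @param reps Replicates per condition.
#' @param main_effects Main-effect settings to cross.
#' @param n_sample Individuals per replicate.
#' @inheritParams type1_main_effects
#' @return A long `coassoc_experiment` tibble with `panel`, the swept
#'   parameter values, `main_effects`, `statistic`, `rate`, `mc_se`.
#' @export
power_curves <- function(panels = c("a", "b", "c", "d"), reps = 1000,
                         main_effects = c("none", "one", "two"),
                         n_sample = 3000,
                         stats = c("fisher", "wz", "calib", "lrt"),
                         alpha = 0.05, seed = 1L,
                         calibration = default_calibration()) {
  panels <- match.arg(panels, several.ok = TRUE)
  grids <- list(
    a = tibble(r = 0, beta3 = c(0.1, 0.2, 0.3, 0.4)),
    b = tibble(r = c(0.2, 0.4, 0.6, 0.8), beta3 = 0),
    c = tibble(r = c(0.2, 0.4, 0.6, 0.8), beta3 = 0.2),
    d = tibble(r = 0.4, beta3 = c(0.1, 0.2, 0.3, 0.4))
  )
  out <- purrr::map(panels, function(pn) {
    grid <- tidyr::expand_grid(grids[[pn]], main_effects = main_effects)
    rows <- purrr::pmap(grid, function(r, beta3, main_effects) {
      m <- pick_feasible_mafs(r, 0.2, 0.3)
      sc <- coassoc_scenario(maf1 = m[1], maf2 = m[2],
                             main_effects = main_effects, r = r, beta3 = beta3,
                             n_sample = n_sample, reps = reps)
      res <- reject_rates(sc, stats, reps, alpha,
                          seed = cell_seed(seed, pn, r, beta3, main_effects),
                          calibration = calibration)
      res$panel <- pn
      res$main_effects <- main_effects
      res
    })
    dplyr::bind_rows(rows)
  })
  as_experiment(dplyr::bind_rows(out), "power_curves")
}

# Fixed LD region used by the robustness study: two blocks of 8 + 9 SNPs
# (genes A and B) with block-wise AR(1) rho = 0.9 plus a shared regional
# factor (cross = 0.5), so adjacent within-gene SNPs sit near latent 0.95
# and between-gene pairs near 0.5 — the structure of two linked genes in a
# strong-LD region. MAFs span 0.25-0.48 with the causal / proxy positions
# pinned to the reference design: arm one's causal SNP is B7 (MAF 0.46),
# tested pair B5-B9; arm two's causal SNPs are A3 (MAF 0.26) and B5
# (MAF 0.48), tested pair A1-B9.
ld_region_spec <- function() {
  mafs <- c(0.30, 0.34, 0.26, 0.38, 0.42, 0.28, 0.36, 0.33,   # gene A (8)
            0.40, 0.27, 0.45, 0.31, 0.48, 0.37, 0.46, 0.29, 0.44) # gene B (9)
  list(mafs = mafs, rho = 0.9, cross = 0.5,
       blocks = rep(c(1L, 2L), c(8L, 9L)), gene = rep(c("A", "B"), c(8, 9)),
       arm_one = list(causal = 15L, tested = c(13L, 17L), or_fixed = NULL),
       arm_two = list(causal = c(3L, 13L), tested = c(1L, 17L), or_fixed = 1.3))
}

#' Linkage-disequilibrium robustness study
#'
#' Asks whether strong LD alone is ever flagged as co-association. Two arms
#' on a simulated 17-SNP two-gene LD region ([simulate_ld_region()] with
#' block-wise AR(1) `rho = 0.9` and a shared regional factor): arm `"one"`
#' has a single causal SNP with odds ratio swept over `or_grid`, and the
#' tested pair are two of its LD neighbours — rejection should stay at the
#' nominal level. Arm `"two"` has two causal SNPs (the second fixed at odds
#' ratio 1.3) in the two genes of the region, and the tested pair are LD
#' proxies of each — here the genotype correlation carries real joint
#' effect and rejection should exceed the null level.
#'
#' @param or_grid Odds ratios for the (first) causal SNP.
#' @param n_sample Individuals per replicate (default 6000).
#' @inheritParams type1_main_effects
#' @return A long `coassoc_experiment` tibble with `arm`, `or`,
#'   `statistic`, `rate`, `mc_se`.
#' @export
ld_effect <- function(reps = 1000, or_grid = c(1.1, 1.2, 1.3, 1.4, 1.5),
                      n_sample = 6000,
                      stats = c("fisher", "wz", "calib"),
                      alpha = 0.05, seed = 1L,
                      calibration = default_calibration()) {
  stats <- match.arg(stats, c("fisher", "wz", "calib", "lrt"), several.ok = TRUE)
  force(calibration)
  region <- ld_region_spec()
  arms <- tidyr::expand_grid(arm = c("one", "two"), or = or_grid)
  rows <- purrr::pmap(arms, function(arm, or) {
    a <- region[[paste0("arm_", arm)]]
    if (arm == "one") {
      b1 <- log(or); b2 <- 0
      beta0 <- solve_beta0(region$mafs[a$causal[1]], 0.3, 0, b1, 0, 0)
    } else {
      b1 <- log(or); b2 <- log(a$or_fixed)
      beta0 <- solve_beta0(region$mafs[a$causal[1]], region$mafs[a$causal[2]],
                           0, b1, b2, 0)   # independence approx for the intercept
    }
    pv <- matrix(NA_real_, reps, length(stats), dimnames = list(NULL, stats))
    withr::with_seed(cell_seed(seed, arm, or), {
      for (i in seq_len(reps)) {
        g <- simulate_ld_region(n_sample, region$mafs, region$blocks,
                                region$rho, region$cross)
        gc1 <- g[[a$causal[1]]]
        gc2 <- if (length(a$causal) > 1) g[[a$causal[2]]] else rep(0L, n_sample)
        ph <- assign_phenotype(gc1, gc2, beta0, b1, b2, 0)
        t1 <- g[[a$tested[1]]]; t2 <- g[[a$tested[2]]]
        case <- ph == 1
        rec <- pair_record(t1[case], t2[case], t1[!case], t2[!case],
                           stats, calibration, g1 = t1, g2 = t2, ph = ph)
        for (s in stats) pv[i, s] <- rec[[paste0("p_", s)]]
      }
    })
    purrr::map_dfr(stats, function(s) {
      p <- pv[, s]; ok <- !is.na(p)
      rate <- mean(p[ok] < alpha)
      tibble(arm = arm, or = or, statistic = s, rate = rate,
             mc_se = sqrt(rate * (1 - rate) / sum(ok)),
             n_reps = sum(ok), n_skipped = sum(!ok),
             n_sample = n_sample, alpha = alpha)
    })
  })
  as_experiment(dplyr::bind_rows(rows), "ld_effect")
}

#' Multi-cohort false-positive study (gain-of-function embedding)
#'
#' Mimics a staged GWAS roadmap: per replicate, a known causal correlated
#' SNP pair (MAFs 0.31/0.30, genotype correlation 0.96, main effects
#' log(1.3) each) is embedded into a background of independent null SNPs;
#' three independent cohorts (sizes `n_cohorts`) are generated and scanned
#' exhaustively. A non-causal pair counts as a false positive only if its
#' p-value beats the causal pair's in *all three* cohorts — the
#' cross-cohort agreement that makes staged designs conservative.
#'
#' @param reps Replicates (default 20 at desk scale; the full design uses
#'   100).
#' @param m_background Number of background null SNPs (default 100; the
#'   full design uses 1000). MAFs are drawn uniformly on (0.1, 0.5).
#' @param n_cohorts Sizes of the three independent cohorts.
#' @inheritParams type1_main_effects
#' @return A `coassoc_experiment` tibble: per statistic, the false-positive
#'   rate over non-causal pairs x replicates (`fp_rate`), the single-cohort
#'   rate for contrast (`fp_rate_single`), and how often the causal pair
#'   ranked first in the largest cohort (`causal_top_rate`).
#' @export
roadmap_fp <- function(reps = 20, m_background = 100,
                       n_cohorts = c(3000, 3000, 6000),
                       stats = c("fisher", "wz", "calib"),
                       seed = 1L, calibration = default_calibration()) {
  stopifnot(m_background >= 0, length(n_cohorts) == 3)
  stats <- match.arg(stats, c("fisher", "wz", "calib", "lrt"), several.ok = TRUE)
  force(calibration)
  causal <- list(maf1 = 0.31, maf2 = 0.30, r = 0.96,
                 beta1 = log(1.3), beta2 = log(1.3))
  latent_rho <- solve_latent_rho(causal$r, causal$maf1, causal$maf2)
  beta0 <- solve_beta0(causal$maf1, causal$maf2, causal$r,
                       causal$beta1, causal$beta2, 0)
  m_total <- m_background + 2L
  n_pairs <- m_total * (m_total - 1L) / 2L
  fp_all <- fp_single <- setNames(numeric(length(stats)), stats)
  causal_top <- setNames(numeric(length(stats)), stats)
  withr::with_seed(seed, {
    for (rep_i in seq_len(reps)) {
      maf_bg <- runif(m_background, 0.1, 0.5)
      # one cohort: causal pair + iid null background, phenotype from the pair
      gen_cohort <- function(n) {
        pair <- simulate_genotype_pair(n, causal$maf1, causal$maf2,
                                       latent_rho = latent_rho)
        bg <- if (m_background > 0) {
          as_tibble(vapply(maf_bg, function(m) rbinom(n, 2L, m), numeric(n)),
                    .name_repair = ~ paste0("bg_", seq_along(maf_bg)))
        } else tibble(.rows = n)
        d <- embed_causal_block(bg, pair)
        d$phenotype <- assign_phenotype(pair$snp1, pair$snp2, beta0,
                                        causal$beta1, causal$beta2, 0)
        d
      }
      pmats <- purrr::map(n_cohorts, function(n) {
        coassoc_scan(gen_cohort(n), stats = stats,
                     calibration = calibration, maf_min = 0.05)
      })
      for (s in stats) {
        pcol <- paste0("p_", s)
        # pairs beating the causal pair, keyed by name so cohorts align
        fp_keys <- purrr::map(pmats, function(sc) {
          ci <- which(sc$snp1 == "snp1" & sc$snp2 == "snp2")
          p <- sc[[pcol]]
          if (length(ci) != 1 || is.na(p[ci])) return(character(0))
          key <- paste(sc$snp1, sc$snp2, sep = "~")
          key[!is.na(p) & p < p[ci] & seq_along(p) != ci]
        })
        fp_single[s] <- fp_single[s] + length(fp_keys[[1]])
        fp_all[s] <- fp_all[s] +
          length(intersect(intersect(fp_keys[[1]], fp_keys[[2]]), fp_keys[[3]]))
        sc3 <- pmats[[3]]
        ci3 <- which(sc3$snp1 == "snp1" & sc3$snp2 == "snp2")
        causal_top[s] <- causal_top[s] +
          as.numeric(length(ci3) == 1 && which.min(sc3[[pcol]]) == ci3)
      }
    }
  })
  out <- purrr::map_dfr(stats, function(s) {
    tibble(statistic = s,
           fp_rate = unname(fp_all[s]) / (n_pairs * reps),
           fp_rate_single = unname(fp_single[s]) / (n_pairs * reps),
           causal_top_rate = unname(causal_top[s]) / reps,
           n_pairs = n_pairs, reps = reps,
           m_background = m_background)
  })
  as_experiment(out, "roadmap_fp")
}
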