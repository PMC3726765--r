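test_that("plain Fisher z-difference follows hand arithmetic and scaling", {
  expect_equal(fisher_cor_test(0.3, 0.3, 500, 700)$stat, 0)
  expect_equal(fisher_cor_test(0.3, 0.3, 500, 700)$p, 1)

  ft <- fisher_cor_test(0.3, 0.1, 1003, 1003)
  expect_equal(ft$stat, 0.2 / sqrt(2 / 1000), tolerance = 1e-12)
  expect_equal(ft$stat, 4.47213595, tolerance = 1e-7)

  # doubling both (n - 3) scales the statistic by sqrt(2)
  ft2 <- fisher_cor_test(0.3, 0.1, 2003, 2003)
  expect_equal(ft2$stat / ft$stat, sqrt(2), tolerance = 1e-12)

  expect_error(fisher_cor_test(0.3, 0.1, 3, 100), class = "coassoc_too_few_samples")
})

test_that("all z statistics are antisymmetric under group swap with invariant p", {
  sp <- make_split_pair(r_ctrl = 0.2, delta = 0.15)
  cal <- test_calibration()
  a <- coassoc_pair_test(sp$g1_case, sp$g2_case, sp$g1_ctrl, sp$g2_ctrl,
                         calibration = cal)
  b <- coassoc_pair_test(sp$g1_ctrl, sp$g2_ctrl, sp$g1_case, sp$g2_case,
                         calibration = cal)
  expect_equal(b$stat_fisher, -a$stat_fisher, tolerance = 1e-12)
  expect_equal(b$stat_wz, -a$stat_wz, tolerance = 1e-12)
  expect_equal(b$stat_calib, -a$stat_calib, tolerance = 1e-12)
  expect_equal(b$p_fisher, a$p_fisher, tolerance = 1e-12)
  expect_equal(b$p_wz, a$p_wz, tolerance = 1e-12)
  expect_equal(b$p_calib, a$p_calib, tolerance = 1e-12)
  expect_equal(b$p_lrt, a$p_lrt, tolerance = 1e-8)

  # identical groups: exact zero
  z <- coassoc_pair_test(sp$g1_case, sp$g2_case, sp$g1_case, sp$g2_case,
                         stats = c("fisher", "wz", "calib"), calibration = cal)
  expect_equal(z$stat_fisher, 0)
  expect_equal(z$stat_wz, 0)
  expect_equal(z$p_fisher, 1)
})

test_that("statistics are invariant to swapping the counted allele", {
  sp <- make_split_pair(r_ctrl = 0.3, delta = 0.1, seed = 7)
  cal <- test_calibration()
  a <- coassoc_pair_test(sp$g1_case, sp$g2_case, sp$g1_ctrl, sp$g2_ctrl,
                         calibration = cal)
  # flip SNP1's counted allele everywhere: r changes sign, |stat| and p do not
  b <- coassoc_pair_test(2 - sp$g1_case, sp$g2_case, 2 - sp$g1_ctrl, sp$g2_ctrl,
                         calibration = cal)
  expect_equal(b$r_case, -a$r_case, tolerance = 1e-12)
  expect_equal(abs(b$stat_fisher), abs(a$stat_fisher), tolerance = 1e-12)
  expect_equal(abs(b$stat_wz), abs(a$stat_wz), tolerance = 1e-12)
  expect_equal(abs(b$stat_calib), abs(a$stat_calib), tolerance = 1e-12)
  expect_equal(b$p_calib, a$p_calib, tolerance = 1e-12)
  expect_equal(b$p_lrt, a$p_lrt, tolerance = 1e-8)
})

test_that("group failures are tagged with the failing group", {
  g1 <- c(0, 1, 2, 0, 1, 2, 1, 0)
  g2 <- c(1, 0, 2, 1, 0, 2, 0, 1)
  mono <- rep(1, 8)
  err <- tryCatch(wz_cor_test(g1, mono, g1, g2), error = identity)
  expect_s3_class(err, "coassoc_zero_variance")
  expect_identical(err$group, "case")
  err2 <- tryCatch(wz_cor_test(g1, g2, g1, mono), error = identity)
  expect_s3_class(err2, "coassoc_zero_variance")
  expect_identical(err2$group, "control")
})

test_that("logistic interaction test behaves under null and alternative", {
  # null: genotype-independent phenotype, chi-square(1) mean ~ 1
  withr::with_seed(5, {
    g <- simulate_genotype_pair(4000, 0.2, 0.3, 0)
    ph <- rbinom(4000, 1, 0.5)
  })
  lt <- lrt_interaction(g$snp1, g$snp2, ph, wald = TRUE)
  expect_gte(lt$p, 0.001)
  expect_equal(unname(lt$stat), unname(lt$wald_stat^2), tolerance = 0.25)

  # strong planted interaction is detected, and power rises with beta3
  withr::with_seed(6, {
    g2 <- simulate_genotype_pair(4000, 0.2, 0.3, 0)
    ph_weak <- assign_phenotype(g2$snp1, g2$snp2, beta0 = -0.3, beta3 = 0.1)
    ph_strong <- assign_phenotype(g2$snp1, g2$snp2, beta0 = -0.4, beta3 = 0.6)
  })
  lt_strong <- lrt_interaction(g2$snp1, g2$snp2, ph_strong)
  expect_lt(lt_strong$p, 1e-4)
  expect_gt(lt_strong$stat, lrt_interaction(g2$snp1, g2$snp2, ph_weak)$stat)

  expect_error(lrt_interaction(g$snp1, g$snp2, rep(1, 4000)),
               class = "coassoc_phenotype_error")
  # perfect separation
  gsep <- c(0, 0, 0, 0, 2, 2, 2, 2)
  err <- tryCatch(lrt_interaction(gsep, gsep, c(0, 0, 0, 0, 1, 1, 1, 1)),
                  error = identity)
  expect_true(inherits(err, "coassoc_separation") ||
              inherits(err, "coassoc_convergence"))
})

test_that("data-frame interface handles missing data and the MAF guard", {
  withr::with_seed(21, {
    sc <- coassoc_scenario(main_effects = "one", r = 0.2, n_sample = 1200)
    d <- draw_study(sc)
  })
  cal <- test_calibration()
  full <- coassoc_test(d, snp1, snp2, phenotype, calibration = cal)
  expect_s3_class(full, "tbl_df")
  expect_identical(nrow(full), 1L)
  expect_identical(full$n_case + full$n_ctrl, nrow(d))

  # punching missing values drops those individuals only
  d2 <- d
  d2$snp1[1:10] <- NA
  part <- coassoc_test(d2, snp1, snp2, phenotype, calibration = cal)
  expect_identical(part$n_case + part$n_ctrl, nrow(d) - 10L)

  # rare SNP refused by default, allowed with warning on override
  d3 <- d
  withr::with_seed(3, d3$snp2 <- rbinom(nrow(d3), 2, 0.01))
  expect_error(coassoc_test(d3, snp1, snp2, phenotype, calibration = cal),
               class = "coassoc_rare_variant")
  expect_warning(
    coassoc_test(d3, snp1, snp2, phenotype, calibration = cal,
                 allow_rare = TRUE, stats = "fisher"),
    class = "coassoc_rare_variant")
})

test_that("calibrated test collapses to the plain Fisher test near independence", {
  cal <- default_calibration()
  withr::with_seed(77, {
    diffs <- replicate(60, {
      g <- simulate_genotype_pair(2400, 0.2, 0.3, 0)
      ph <- rbinom(2400, 1, 0.5)
      case <- ph == 1
      r <- coassoc_pair_test(g$snp1[case], g$snp2[case],
                             g$snp1[!case], g$snp2[!case],
                             stats = c("fisher", "calib"), calibration = cal)
      abs(r$stat_calib - r$stat_fisher)
    })
  })
  expect_gte(mean(diffs < 0.05), 0.95)
})
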