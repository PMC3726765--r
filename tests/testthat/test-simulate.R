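test_that("copula pair hits HWE margins and the target correlation", {
  withr::with_seed(19, {
    g <- simulate_genotype_pair(1e5, 0.2, 0.3, 0.4)
  })
  expect_equal(cor(g$snp1, g$snp2), 0.4, tolerance = 0.02)
  expect_equal(mean(g$snp1) / 2, 0.2, tolerance = 0.02)
  expect_equal(mean(g$snp2) / 2, 0.3, tolerance = 0.02)
  # HWE genotype class frequencies, e.g. P(G = 2) ~ maf^2
  expect_lt(abs(mean(g$snp1 == 2) - 0.04), 0.005)
  chi <- suppressWarnings(chisq.test(table(factor(g$snp2, levels = 0:2)),
                                     p = c(0.49, 0.42, 0.09)))
  expect_gt(chi$p.value, 0.001)

  withr::with_seed(20, {
    g0 <- simulate_genotype_pair(1e5, 0.2, 0.3, 0)
  })
  expect_lt(abs(cor(g0$snp1, g0$snp2)), 0.02)
})

test_that("latent correlation inversion matches a brute-force integration oracle", {
  rho <- coassoc:::solve_latent_rho(0.4, 0.2, 0.3)
  # oracle: 2-D Riemann sum of the bivariate normal density over a fine grid
  z <- seq(-6, 6, length.out = 1201)
  h <- z[2] - z[1]
  dens <- function(z1, z2, rho) {
    s <- 1 - rho^2
    exp(-(z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * s)) / (2 * pi * sqrt(s))
  }
  t1 <- coassoc:::genotype_cutpoints(0.2)
  t2 <- coassoc:::genotype_cutpoints(0.3)
  gclass <- function(zz, t) (zz >= t[1]) + (zz >= t[2])
  g1 <- gclass(z, t1); g2 <- gclass(z, t2)
  d <- outer(z, z, dens, rho = rho) * h^2
  e12 <- sum(outer(g1, g2) * d)
  e1 <- sum(g1 * rowSums(d)); e2 <- sum(g2 * colSums(d))
  v1 <- sum(g1^2 * rowSums(d)) - e1^2
  v2 <- sum(g2^2 * colSums(d)) - e2^2
  r_oracle <- (e12 - e1 * e2) / sqrt(v1 * v2)
  expect_equal(r_oracle, 0.4, tolerance = 1e-3)
  # and the forward map agrees with the oracle at the solved rho
  expect_equal(coassoc:::copula_genotype_cor(rho, 0.2, 0.3), 0.4, tolerance = 1e-6)
})

test_that("infeasible correlations are refused with the attainable interval", {
  err <- tryCatch(simulate_genotype_pair(100, 0.2, 0.3, 0.9), error = identity)
  expect_s3_class(err, "coassoc_infeasible_correlation")
  expect_true(err$bounds[2] < 0.9 && err$bounds[2] > 0.7)
  # the bound itself is the comonotone-coupling correlation (hand value)
  expect_equal(feasible_cor_range(0.2, 0.3)[2], 0.29 / sqrt(0.32 * 0.42),
               tolerance = 1e-3)
})

test_that("LD block has AR(1)-decaying correlation and is seed-deterministic", {
  mafs <- rep(0.3, 10)
  b1 <- simulate_ld_block(2e4, mafs, 0.9, seed = 5)
  b2 <- simulate_ld_block(2e4, mafs, 0.9, seed = 5)
  expect_identical(b1, b2)
  r12 <- cor(b1$snp_1, b1$snp_2)
  r1_10 <- cor(b1$snp_1, b1$snp_10)
  expect_gt(r12, r1_10)
  expect_gt(r12, 0.5)
  b0 <- simulate_ld_block(1e5, rep(0.3, 4), 0, seed = 6)
  expect_lt(max(abs(cor(as.matrix(b0))[upper.tri(diag(4))])), 0.02)
})

test_that("phenotype model matches the closed-form genotype mixture", {
  # enumeration over the three genotype classes at MAF 0.2, beta = (-1, 0.3)
  pg <- c(0.64, 0.32, 0.04)
  prev_closed <- sum(pg * plogis(-1 + 0.3 * (0:2)))
  withr::with_seed(9, {
    g1 <- rbinom(2e5, 2, 0.2)
    ph <- assign_phenotype(g1, rep(0L, 2e5), beta0 = -1, beta1 = 0.3)
  })
  expect_equal(mean(ph), prev_closed, tolerance = 0.005)
  # all-zero coefficients: prevalence one half
  withr::with_seed(10, {
    ph0 <- assign_phenotype(g1, g1, beta0 = 0)
  })
  expect_equal(mean(ph0), 0.5, tolerance = 0.005)
  # solve_beta0 inverts the same mixture
  b0 <- solve_beta0(0.2, 0.3, 0, beta1 = 0.3, prevalence = prev_closed)
  expect_equal(b0, -1, tolerance = 1e-6)
})

test_that("scenario objects resolve intercept, taxonomy label and feasibility", {
  sc <- coassoc_scenario(main_effects = "two", r = 0.4, beta3 = 0.2,
                         n_sample = 1000)
  expect_identical(sc$coassoc_type, "III")
  expect_equal(sc$beta1, log(1.3)); expect_equal(sc$beta2, log(1.3))
  expect_identical(coassoc_scenario(beta3 = 0.2)$coassoc_type, "I")
  expect_identical(coassoc_scenario(main_effects = "one", r = 0.3)$coassoc_type, "II")
  expect_identical(coassoc_scenario(r = 0.3)$coassoc_type, "null")
  expect_error(coassoc_scenario(r = 0.9), class = "coassoc_infeasible_correlation")
  # solved intercept gives ~50% prevalence in a large draw
  withr::with_seed(13, {
    big <- draw_study(coassoc_scenario(main_effects = "two", r = 0.4,
                                       n_sample = 3000))
  })
  expect_lt(abs(mean(big$phenotype) - 0.5), 0.035)
})

test_that("draw_study is deterministic given a seed and respects its size", {
  sc <- coassoc_scenario(main_effects = "one", n_sample = 500, n_population = 1500)
  a <- draw_study(sc, seed = 101)
  b <- draw_study(sc, seed = 101)
  expect_identical(a$snp1, b$snp1)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(nrow(a), 500L)
  expect_true(all(c("snp1", "snp2", "phenotype") %in% names(a)))
  ach <- attr(a, "achieved")
  expect_equal(unname(ach["maf1"]), 0.2, tolerance = 0.06)
})

test_that("embedding a causal block preserves columns and flags them", {
  withr::with_seed(3, {
    bg <- tibble::tibble(b1 = rbinom(50, 2, 0.3), b2 = rbinom(50, 2, 0.4))
    blk <- simulate_genotype_pair(50, 0.3, 0.3, 0.5)
  })
  emb <- embed_causal_block(bg, blk)
  expect_identical(attr(emb, "causal"), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(emb$snp1, blk$snp1)  # columns untouched
  expect_identical(emb$b1, bg$b1)
  # empty block is the identity on the columns
  same <- embed_causal_block(bg, bg[, 0])
  expect_identical(names(same), names(bg))
  expect_identical(same$b1, bg$b1)
  expect_identical(attr(same, "causal"), c(FALSE, FALSE))
  expect_error(embed_causal_block(bg, blk[1:10, ]), class = "coassoc_row_mismatch")
})
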