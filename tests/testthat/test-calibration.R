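test_that("variance grid is reproducible and near 1 at independence", {
  grid_args <- list(maf_pairs = data.frame(maf1 = 0.2, maf2 = 0.3),
                    r_grid = c(0, 0.4), n_cal = 1500, reps_cal = 60, seed = 11L)
  g1 <- do.call(empirical_variance_grid, grid_args)
  g2 <- do.call(empirical_variance_grid, grid_args)
  expect_identical(g1$rel_var, g2$rel_var)   # bit-identical under same seed
  expect_identical(g1$z_bar, g2$z_bar)

  # r = 0 point: relative variance ~ 1 (Fisher normal-theory value);
  # 60 replicates give a variance SE of ~18%, so a wide but real band
  expect_equal(g1$rel_var[g1$r_target == 0], 1, tolerance = 0.45)
  expect_equal(g1$z_bar[g1$r_target == 0], 0, tolerance = 0.05)

  # infeasible points are skipped with a warning, not fatal
  expect_warning(
    gg <- empirical_variance_grid(data.frame(maf1 = 0.2, maf2 = 0.3),
                                  r_grid = c(0, 0.9), n_cal = 1500,
                                  reps_cal = 30, seed = 2L),
    class = "coassoc_infeasible_correlation")
  expect_identical(nrow(gg), 1L)
})

test_that("log-variance fit recovers a known quadratic law and degenerates sanely", {
  # synthetic grid from a known even quadratic law (f(0) = 1) with noise
  withr::with_seed(8, {
    z <- rep(seq(0, 1.2, length.out = 12), each = 3)
    true <- c(b = -0.3, c = 0.9)
    lv <- true["b"] * abs(z) + true["c"] * z^2 + rnorm(length(z), 0, 0.02)
  })
  grid <- tibble::tibble(maf1 = 0.2, maf2 = 0.3, r_target = tanh(z),
                         z_bar = z, rel_var = exp(lv), n_cal = 5000L,
                         reps_cal = 500L)
  fit <- fit_logvar(grid)
  se <- sqrt(diag(vcov(lm(lv ~ 0 + abs(z) + I(z^2)))))
  expect_identical(fit$coef[["a"]], 0)
  expect_lt(abs(fit$coef[["b"]] - true[["b"]]), 2 * se[1])
  expect_lt(abs(fit$coef[["c"]] - true[["c"]]), 2 * se[2])

  # all-ones grid: coefficients ~ 0, predict ~ 1
  flat <- tibble::tibble(maf1 = 0.2, maf2 = 0.3, r_target = tanh(z),
                         z_bar = z, rel_var = 1, n_cal = 5000L, reps_cal = 500L)
  fit0 <- fit_logvar(flat)
  expect_equal(unname(fit0$coef), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(predict_f(fit0, c(-1, 0, 0.5)), c(1, 1, 1), tolerance = 1e-10)

  # fewer than 3 distinct z values is rank-deficient
  bad <- dplyr::mutate(flat[1:10, ], z_bar = rep(c(0, 0.5), 5))
  expect_error(fit_logvar(bad), class = "coassoc_rank_deficient")
})

test_that("predict_f is even, positive, and warns on extrapolation", {
  cal <- test_calibration()
  zz <- seq(-1, 1, by = 0.25)
  suppressWarnings({
    expect_equal(predict_f(cal, zz), predict_f(cal, -zz), tolerance = 1e-12)
    expect_true(all(predict_f(cal, zz) > 0))
  }, classes = "coassoc_calibration_range")
  expect_warning(predict_f(cal, cal$z_range[2] + 1),
                 class = "coassoc_calibration_range")
  # deterministic given coefficients
  expect_identical(predict_f(cal, 0.3), predict_f(cal, 0.3))
})

test_that("calibration round-trips through the plain-text artifact", {
  cal <- test_calibration()
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$coef, cal$coef, tolerance = 1e-15)
  expect_equal(back$z_range, cal$z_range, tolerance = 1e-12)
  expect_identical(back$n_cal, cal$n_cal)
  expect_identical(back$reps_cal, cal$reps_cal)
  expect_equal(back$grid$rel_var, cal$grid$rel_var, tolerance = 1e-12)
  # identical predictions after the round trip
  zz <- seq(0, 1.5, by = 0.1)
  suppressWarnings(
    expect_equal(predict_f(back, zz), predict_f(cal, zz), tolerance = 1e-12),
    classes = "coassoc_calibration_range")
})

test_that("the shipped default model is sane", {
  cal <- default_calibration()
  expect_s3_class(cal, "coassoc_calibration")
  # f(0) = 1: the fast test matches plain Fisher at independence
  expect_identical(predict_f(cal, 0), 1)
  expect_gt(predict_f(cal, 0), 0.8)
  expect_lt(predict_f(cal, 0), 1.25)
  expect_gte(nrow(cal$grid), 40)
  expect_gte(max(cal$grid$r_target), 0.9)
  # inflation at high correlation: increasing over the upper half of range
  zu <- seq(cal$z_range[2] / 2, cal$z_range[2], length.out = 20)
  expect_true(all(diff(predict_f(cal, zu)) > 0))
  expect_gt(predict_f(cal, cal$z_range[2]), predict_f(cal, 0))
  # cached accessor returns the same object
  expect_identical(default_calibration(), cal)
})

test_that("tidy and glance expose the calibration fit", {
  cal <- test_calibration()
  td <- tidy(cal)
  expect_identical(td$term, c("(Intercept)", "abs(z)", "z^2"))
  expect_identical(td$estimate, as.numeric(cal$coef))
  gl <- glance(cal)
  expect_identical(gl$n_grid, nrow(cal$grid))
  expect_gte(gl$r.squared, 0)
})
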