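# Shared fixtures, built in code.

# Small calibration model for interface tests (the shipped artifact is used
# where the statistical behaviour of the default model matters).
test_calibration <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) {
      cal <<- suppressWarnings(calibrate_coassoc(
        maf_pairs = data.frame(maf1 = c(0.2, 0.2, 0.3), maf2 = c(0.3, 0.4, 0.3)),
        r_grid = c(0, 0.25, 0.5, 0.7), n_cal = 1500, reps_cal = 60, seed = 424L))
    }
    cal
  }
})

# A deterministic genotype pair with case/control groups and a planted
# correlation difference (delta on the case side).
make_split_pair <- function(n_case = 600, n_ctrl = 600, r_ctrl = 0.2,
                            delta = 0, maf1 = 0.2, maf2 = 0.3, seed = 99) {
  withr::with_seed(seed, {
    ca <- simulate_genotype_pair(n_case, maf1, maf2, min(r_ctrl + delta, 0.75))
    co <- simulate_genotype_pair(n_ctrl, maf1, maf2, r_ctrl)
    list(g1_case = ca$snp1, g2_case = ca$snp2,
         g1_ctrl = co$snp1, g2_ctrl = co$snp2)
  })
}

# Brute-force central joint moment by explicit double loop over individuals.
naive_moment <- function(x, y, j, k) {
  mx <- mean(x); my <- mean(y)
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - mx)^j * (y[i] - my)^k
  acc / length(x)
}

# Brute-force Benjamini-Hochberg step-up.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
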