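scan_fixture <- function(m_null = 4, n = 600, seed = 55, delta = 0.35) {
  # planted type-II-like pair (snp1, snp2) + independent null SNPs
  withr::with_seed(seed, {
    n_case <- n %/% 2; n_ctrl <- n - n %/% 2
    ca <- simulate_genotype_pair(n_case, 0.2, 0.3, 0.2 + delta)
    co <- simulate_genotype_pair(n_ctrl, 0.2, 0.3, 0.2)
    d <- dplyr::bind_rows(ca, co)
    d$phenotype <- rep(c(1L, 0L), c(n_case, n_ctrl))
    for (j in seq_len(m_null)) d[[paste0("null", j)]] <- rbinom(n, 2, 0.3)
  })
  d
}

test_that("scan emits all pairs in deterministic order with annotated skips", {
  d <- scan_fixture(m_null = 4)
  cal <- test_calibration()
  res <- coassoc_scan(d, stats = c("fisher", "wz", "calib"), calibration = cal)
  m <- 6L
  expect_identical(nrow(res), as.integer(m * (m - 1L) / 2L))
  expect_identical(res$snp1[1], "snp1")
  # column-index lexicographic ordering
  first <- match(res$snp1, unique(c(res$snp1, res$snp2)))
  expect_true(all(diff(first) >= 0))
  expect_true(all(is.na(res$skip_reason)))

  # a SNP monomorphic among cases is skipped with the group recorded
  d2 <- d
  d2$null1[d2$phenotype == 1] <- 1L
  res2 <- coassoc_scan(d2, stats = "fisher", calibration = cal, maf_min = 0)
  skipped <- dplyr::filter(res2, snp1 == "null1" | snp2 == "null1")
  expect_true(all(skipped$skip_reason == "zero_variance:case"))
  expect_true(all(is.na(skipped$p_fisher)))
  kept <- dplyr::filter(res2, snp1 != "null1", snp2 != "null1")
  expect_true(all(!is.na(kept$p_fisher)))
})

test_that("scan results are invariant to SNP column order", {
  d <- scan_fixture(m_null = 3)
  cal <- test_calibration()
  a <- coassoc_scan(d, stats = c("fisher", "calib"), calibration = cal)
  snp_cols <- setdiff(names(d), "phenotype")
  d_shuf <- d[c(rev(snp_cols), "phenotype")]
  b <- coassoc_scan(d_shuf, stats = c("fisher", "calib"), calibration = cal)
  key <- function(x) paste(pmin(x$snp1, x$snp2), pmax(x$snp1, x$snp2))
  bb <- b[match(key(a), key(b)), ]
  expect_equal(abs(bb$stat_fisher), abs(a$stat_fisher), tolerance = 1e-12)
  expect_equal(bb$p_calib, a$p_calib, tolerance = 1e-12)
})

test_that("planted co-association pair ranks above null pairs", {
  cal <- default_calibration()
  top_hits <- vapply(1:20, function(i) {
    d <- scan_fixture(m_null = 5, n = 1200, seed = 700 + i)
    res <- coassoc_scan(d, stats = "wz", calibration = cal)
    res_ok <- dplyr::filter(res, !is.na(p_wz))
    best <- res_ok[which.min(res_ok$p_wz), ]
    best$snp1 == "snp1" && best$snp2 == "snp2"
  }, logical(1))
  expect_gte(mean(top_hits), 0.95)
})

test_that("MAF filtering, gene restriction and the LRT guard apply", {
  d <- scan_fixture(m_null = 2)
  withr::with_seed(1, d$rare <- rbinom(nrow(d), 2, 0.01))
  cal <- test_calibration()
  expect_message(res <- coassoc_scan(d, stats = "fisher", calibration = cal),
                 "MAF")
  expect_false(any(res$snp1 == "rare" | res$snp2 == "rare"))

  info <- tibble::tibble(snp = c("snp1", "snp2", "null1", "null2"),
                         gene = c("A", "A", "B", "B"))
  res_bg <- coassoc_scan(d[c("snp1", "snp2", "null1", "null2", "phenotype")],
                         stats = "fisher", calibration = cal,
                         pairs = "between-gene", snp_info = info)
  expect_identical(nrow(res_bg), 4L)
  expect_true(all(res_bg$gene1 != res_bg$gene2))

  expect_error(coassoc_scan(d, stats = "lrt", calibration = cal,
                            max_lrt_pairs = 2L),
               class = "coassoc_config_error")
})

test_that("p-value adjustment matches brute-force oracles", {
  p <- c(0.01, 0.02, 0.04, 0.8)
  expect_identical(adjust_pvalues(p, "none"), p)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)  # single p unchanged
  expect_equal(adjust_pvalues(c(0.03, 0.4), "bonferroni"), c(0.06, 0.8))
  expect_equal(adjust_pvalues(p, "bh"), naive_bh(p), tolerance = 1e-12)
  withr::with_seed(2, pr <- runif(50))
  expect_equal(adjust_pvalues(pr, "bh"), naive_bh(pr), tolerance = 1e-12)

  d <- scan_fixture(m_null = 2)
  res <- coassoc_scan(d, stats = "fisher", calibration = test_calibration(),
                      adjust = "bh")
  expect_equal(res$p_fisher_adj, naive_bh(res$p_fisher), tolerance = 1e-12)
})

test_that("scan output writes annotated TSV and glance summarises it", {
  d <- scan_fixture(m_null = 2)
  cal <- test_calibration()
  res <- coassoc_scan(d, stats = c("fisher", "calib"), calibration = cal)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan(res, path, calibration = cal)
  hdr <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("stats: fisher,calib", hdr)))
  body <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_identical(nrow(body), nrow(res))
  gl <- glance(res)
  expect_identical(gl$n_pairs, nrow(res))
  expect_equal(gl$min_p_fisher, min(res$p_fisher, na.rm = TRUE))
})

test_that("scan throughput supports exhaustive use at study scale", {
  # calibrated-statistic path on a 1220-individual cohort
  withr::with_seed(66, {
    n <- 1220
    d <- tibble::as_tibble(
      vapply(1:46, function(j) rbinom(n, 2, runif(1, 0.1, 0.5)), numeric(n)),
      .name_repair = ~ paste0("s", 1:46))
    d$phenotype <- rep(c(1L, 0L), c(706, 514))
  })
  cal <- default_calibration()
  t0 <- proc.time()["elapsed"]
  res <- coassoc_scan(d, stats = "calib", calibration = cal)
  elapsed <- proc.time()["elapsed"] - t0
  expect_identical(nrow(res), 1035L)  # 46 * 45 / 2 pairs
  pairs_per_min <- nrow(res) / (elapsed / 60)
  expect_gt(pairs_per_min, 1e4)
})
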