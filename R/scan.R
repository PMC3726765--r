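# Exhaustive pairwise scan. The per-pair kernel lives here so the scan and
# the simulation experiments share exactly the same statistic code path.

# Fast per-group moment-based variance of z-hat (identical algebra to
# wz_variance_z(joint_moments(x, y)); kept loop-free for the scan and the
# replicate drivers). Raises the same classed conditions.
wz_var_fast <- function(x, y, group = "a") {
  n <- length(x)
  if (n < 4L) abort_too_few_samples(n, group)
  dx <- x - mean(x); dy <- y - mean(y)
  dx2 <- dx * dx; dy2 <- dy * dy
  mu20 <- mean(dx2); mu02 <- mean(dy2)
  if (mu20 == 0 || mu02 == 0) abort_zero_variance(group)
  mu11 <- mean(dx * dy)
  r <- mu11 / sqrt(mu20 * mu02)
  if (abs(r) > 1 - 1e-8) abort_degenerate_correlation(r, group)
  mu22 <- mean(dx2 * dy2)
  if (abs(r) < 1e-4) {
    n_var_r <- mu22 / (mu20 * mu02)
  } else {
    mu40 <- mean(dx2 * dx2); mu04 <- mean(dy2 * dy2)
    mu31 <- mean(dx2 * dx * dy); mu13 <- mean(dx * dy * dy2)
    n_var_r <- r^2 * (mu40 / (4 * mu20^2) + mu04 / (4 * mu02^2) +
                      mu22 / (2 * mu20 * mu02) + mu22 / mu11^2 -
                      mu31 / (mu11 * mu20) - mu13 / (mu11 * mu02))
  }
  if (!is.finite(n_var_r) || n_var_r <= 0) {
    coassoc_abort("numerical_instability",
      sprintf("moment-based variance not positive in %s group", group))
  }
  (n_var_r / n) / (1 - r^2)^2
}

# One SNP pair, all requested statistics, no tibble overhead. Returns a
# plain list of fields; statistical refusals land in skip_reason instead of
# propagating.
pair_record <- function(g1_case, g2_case, g1_ctrl, g2_ctrl, stats, calibration,
                        g1 = NULL, g2 = NULL, ph = NULL) {
  rec <- list(n_case = length(g1_case), n_ctrl = length(g1_ctrl),
              r_case = NA_real_, r_ctrl = NA_real_,
              z_case = NA_real_, z_ctrl = NA_real_,
              stat_fisher = NA_real_, p_fisher = NA_real_,
              stat_wz = NA_real_, p_wz = NA_real_,
              stat_calib = NA_real_, p_calib = NA_real_,
              stat_lrt = NA_real_, p_lrt = NA_real_,
              skip_reason = NA_character_)
  tryCatch({
    if (rec$n_case < 4L) abort_too_few_samples(rec$n_case, "case")
    if (rec$n_ctrl < 4L) abort_too_few_samples(rec$n_ctrl, "control")
    if (var(g1_case) == 0 || var(g2_case) == 0) abort_zero_variance("case")
    if (var(g1_ctrl) == 0 || var(g2_ctrl) == 0) abort_zero_variance("control")
    rc <- cor(g1_case, g2_case)
    rt <- cor(g1_ctrl, g2_ctrl)
    if (abs(rc) > 1 - 1e-8) abort_degenerate_correlation(rc, "case")
    if (abs(rt) > 1 - 1e-8) abort_degenerate_correlation(rt, "control")
    rec$r_case <- rc; rec$r_ctrl <- rt
    rec$z_case <- atanh(rc); rec$z_ctrl <- atanh(rt)
    if ("fisher" %in% stats) {
      s <- (rec$z_case - rec$z_ctrl) /
        sqrt(1 / (rec$n_case - 3) + 1 / (rec$n_ctrl - 3))
      rec$stat_fisher <- s; rec$p_fisher <- p_two_sided(s)
    }
    if ("wz" %in% stats) {
      v <- wz_var_fast(g1_case, g2_case, "case") +
           wz_var_fast(g1_ctrl, g2_ctrl, "control")
      s <- (rec$z_case - rec$z_ctrl) / sqrt(v)
      rec$stat_wz <- s; rec$p_wz <- p_two_sided(s)
    }
    if ("calib" %in% stats) {
      if (is.null(g1)) { g1 <- c(g1_case, g1_ctrl); g2 <- c(g2_case, g2_ctrl) }
      rp <- cor(g1, g2)
      if (abs(rp) > 1 - 1e-8) abort_degenerate_correlation(rp, "pooled")
      f <- predict_f(calibration, atanh(rp))
      s <- (rec$z_case - rec$z_ctrl) /
        sqrt(f * (1 / (rec$n_case - 3) + 1 / (rec$n_ctrl - 3)))
      rec$stat_calib <- s; rec$p_calib <- p_two_sided(s)
    }
    if ("lrt" %in% stats) {
      if (is.null(g1)) { g1 <- c(g1_case, g1_ctrl); g2 <- c(g2_case, g2_ctrl) }
      if (is.null(ph)) ph <- rep(c(1L, 0L), c(rec$n_case, rec$n_ctrl))
      lt <- lrt_interaction(g1, g2, ph)
      rec$stat_lrt <- lt$stat; rec$p_lrt <- lt$p
    }
    rec
  }, coassoc_error = function(e) {
    rec$skip_reason <- sub("^coassoc_", "", class(e)[1])
    if (!is.null(e$group)) rec$skip_reason <- paste0(rec$skip_reason, ":", e$group)
    rec
  })
}

#' Exhaustive pairwise co-association scan
#'
#' Tests every pair of SNP columns (or a restricted set) of a case-control
#' genotype tibble with the selected statistics, handling missing data
#' pairwise per group and recording a `skip_reason` for untestable pairs
#' (monomorphic in a group, degenerate correlation, too few complete
#' observations). Pairs are emitted in column-index lexicographic order, so
#' results are invariant to SNP column order up to row reordering.
#'
#' @param data Tibble of individuals: a binary `phenotype` column plus
#'   0/1/2 SNP columns (as from [read_genotypes()] or [draw_study()]).
#' @param phenotype Phenotype column (tidy-eval; default `phenotype`).
#' @param stats Statistics to run, subset of
#'   `c("fisher", "wz", "calib", "lrt")`.
#' @param calibration Calibration model for `"calib"`.
#' @param maf_min SNPs below this pooled minor allele frequency are excluded
#'   before pairing (default 0.05).
#' @param snps Optional character vector restricting the scan to these SNP
#'   columns.
#' @param pairs `"all"` or `"between-gene"` (requires gene annotation via
#'   `snp_info`).
#' @param snp_info Optional tibble `snp`, `gene` for annotation; defaults to
#'   the `snp_info` attribute left by [read_genotypes()].
#' @param adjust Multiple-testing adjustment appended per statistic:
#'   `"none"` (default, raw p-values only), `"bonferroni"`, or `"bh"`.
#' @param max_lrt_pairs Refuse to run the logistic interaction test on more
#'   pairs than this (it dominates runtime on large scans).
#' @return A tibble of class `coassoc_scan`: one row per pair with columns
#'   `snp1 snp2 gene1 gene2 n_case n_ctrl r_case r_ctrl z_case z_ctrl` plus
#'   `stat_*`/`p_*` for each selected statistic, `skip_reason`, and
#'   `p_*_adj` when `adjust != "none"`.
#' @export
coassoc_scan <- function(data, phenotype = phenotype,
                         stats = c("fisher", "wz", "calib"),
                         calibration = default_calibration(),
                         maf_min = 0.05, snps = NULL,
                         pairs = c("all", "between-gene"),
                         snp_info = attr(data, "snp_info"),
                         adjust = c("none", "bonferroni", "bh"),
                         max_lrt_pairs = 50000L) {
  stats <- match.arg(stats, c("fisher", "wz", "calib", "lrt"), several.ok = TRUE)
  pairs <- match.arg(pairs)
  adjust <- match.arg(adjust)
  ph <- dplyr::pull(data, {{ phenotype }})
  if (!all(ph %in% c(0, 1), na.rm = TRUE)) {
    coassoc_abort("phenotype_error", "phenotype must be binary 0/1")
  }
  ph_name <- names(dplyr::select(as_tibble(data)[0, ], {{ phenotype }}))
  snp_cols <- setdiff(names(data), c(ph_name, "sample_id"))
  if (!is.null(snps)) snp_cols <- intersect(snp_cols, snps)
  keep_ind <- !is.na(ph)
  g_all <- as.matrix(as_tibble(data)[keep_ind, snp_cols, drop = FALSE])
  ph <- ph[keep_ind]

  maf <- apply(g_all, 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2; min(p, 1 - p)
  })
  dropped <- snp_cols[maf < maf_min]
  if (length(dropped) > 0) {
    message(sprintf("excluding %d SNP(s) with MAF < %.3f", length(dropped), maf_min))
  }
  snp_cols <- snp_cols[maf >= maf_min]
  if (length(snp_cols) < 2L) {
    coassoc_abort("no_testable_pairs", "fewer than 2 SNPs survive the MAF filter")
  }
  g_all <- g_all[, snp_cols, drop = FALSE]

  gene_of <- rep(NA_character_, length(snp_cols))
  if (!is.null(snp_info) && "gene" %in% names(snp_info)) {
    gene_of <- snp_info$gene[match(snp_cols, snp_info$snp)]
  }
  idx <- utils::combn(length(snp_cols), 2L)
  if (pairs == "between-gene") {
    if (all(is.na(gene_of))) {
      coassoc_abort("no_testable_pairs", "between-gene restriction requires gene annotation in snp_info")
    }
    keep <- gene_of[idx[1, ]] != gene_of[idx[2, ]]
    keep[is.na(keep)] <- FALSE
    idx <- idx[, keep, drop = FALSE]
  }
  n_pairs <- ncol(idx)
  if (n_pairs == 0L) coassoc_abort("no_testable_pairs", "no SNP pairs to test")
  if ("lrt" %in% stats && n_pairs > max_lrt_pairs) {
    coassoc_abort("config_error",
      sprintf("lrt requested on %d pairs (> max_lrt_pairs = %d); raise the guard or drop lrt",
              n_pairs, max_lrt_pairs))
  }

  is_case <- ph == 1
  recs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- idx[1, k]; j <- idx[2, k]
    g1 <- g_all[, i]; g2 <- g_all[, j]
    ok <- !is.na(g1) & !is.na(g2)   # pairwise complete case, per pair
    g1 <- g1[ok]; g2 <- g2[ok]; case_k <- is_case[ok]
    recs[[k]] <- pair_record(g1[case_k], g2[case_k], g1[!case_k], g2[!case_k],
                             stats, calibration,
                             g1 = g1, g2 = g2, ph = as.integer(case_k))
  }
  out <- dplyr::bind_rows(lapply(recs, as_tibble))
  out <- dplyr::bind_cols(
    tibble(snp1 = snp_cols[idx[1, ]], snp2 = snp_cols[idx[2, ]],
           gene1 = gene_of[idx[1, ]], gene2 = gene_of[idx[2, ]]),
    out
  )
  drop_cols <- setdiff(c("fisher", "wz", "calib", "lrt"), stats)
  out <- out[setdiff(names(out), c(paste0("stat_", drop_cols), paste0("p_", drop_cols)))]
  if (adjust != "none") {
    for (s in stats) {
      out[[paste0("p_", s, "_adj")]] <- adjust_pvalues(out[[paste0("p_", s)]], adjust)
    }
  }
  class(out) <- c("coassoc_scan", class(out))
  attr(out, "config") <- list(stats = stats, maf_min = maf_min, pairs = pairs,
                              adjust = adjust, n_snps = length(snp_cols),
                              dropped_maf = dropped)
  out
}

#' Multiple-testing adjustment
#'
#' `"bonferroni"` is `min(1, m p)`, `"bh"` the Benjamini-Hochberg step-up,
#' `"none"` the identity. `NA` p-values (skipped pairs) are passed through
#' and do not count toward `m`.
#'
#' @param p Vector of p-values in (0, 1], `NA` allowed.
#' @param method `"none"`, `"bonferroni"`, or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "bh")) {
  method <- match.arg(method)
  switch(method,
    none = p,
    bonferroni = p.adjust(p, method = "bonferroni"),
    bh = p.adjust(p, method = "BH"))
}

#' Write scan results as annotated TSV
#'
#' Emits `# key: value` metadata lines (package version, configuration,
#' calibration provenance) followed by the results table.
#'
#' @param x A [coassoc_scan()] result.
#' @param path Output file.
#' @param calibration Calibration model whose provenance to record.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path, calibration = NULL) {
  cfg <- attr(x, "config")
  hdr <- c(provenance_header(),
           sprintf("# stats: %s", paste(cfg$stats, collapse = ",")),
           sprintf("# maf_min: %g", cfg$maf_min),
           sprintf("# pairs: %s", cfg$pairs),
           sprintf("# adjust: %s", cfg$adjust),
           sprintf("# n_snps: %d", cfg$n_snps))
  if (!is.null(calibration)) {
    hdr <- c(hdr, sprintf("# calibration: seed=%s n_cal=%d reps_cal=%d",
                          format(calibration$seed), calibration$n_cal,
                          calibration$reps_cal))
  }
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
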