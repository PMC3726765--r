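# Classed conditions used across the package. Every statistical refusal
# (monomorphic SNP, degenerate correlation, too few samples, ...) carries a
# class so the scan layer can convert it into a skip_reason instead of dying.

coassoc_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("coassoc_", class), "coassoc_error"), ...)
}

coassoc_warn <- function(class, message, ...) {
  rlang::warn(message, class = c(paste0("coassoc_", class), "coassoc_warning"), ...)
}

#' @noRd
abort_zero_variance <- function(group) {
  coassoc_abort("zero_variance",
    sprintf("monomorphic genotype vector (zero variance) in %s group", group),
    group = group)
}

abort_length_mismatch <- function(n1, n2) {
  coassoc_abort("length_mismatch",
    sprintf("genotype vectors have different lengths (%d vs %d)", n1, n2))
}

abort_too_few_samples <- function(n, group = "a") {
  coassoc_abort("too_few_samples",
    sprintf("need at least 4 individuals per group, got %d in %s group", n, group),
    group = group)
}

abort_degenerate_correlation <- function(r, group = "a") {
  coassoc_abort("degenerate_correlation",
    sprintf("|r| = %.10g too close to 1 in %s group; pair is an uninformative duplicate",
            abs(r), group),
    group = group)
}

abort_infeasible_correlation <- function(r_target, bounds) {
  coassoc_abort("infeasible_correlation",
    sprintf("target genotype correlation %.3f outside attainable interval [%.4f, %.4f] for these allele frequencies",
            r_target, bounds[1], bounds[2]),
    bounds = bounds)
}

# Checks shared by every statistic: additive coding, equal lengths, n, variance.
check_genotype_vectors <- function(x, y, group = "a") {
  if (length(x) != length(y)) abort_length_mismatch(length(x), length(y))
  if (length(x) < 4L) abort_too_few_samples(length(x), group)
  if (anyNA(x) || anyNA(y)) {
    coassoc_abort("missing_values",
      sprintf("missing genotypes in %s group after complete-case filtering", group))
  }
  if (!all(x %in% c(0, 1, 2)) || !all(y %in% c(0, 1, 2))) {
    coassoc_abort("bad_coding",
      sprintf("genotypes must be additive minor-allele counts in {0,1,2} (%s group)", group))
  }
  if (var(x) == 0) abort_zero_variance(group)
  if (var(y) == 0) abort_zero_variance(group)
  invisible(TRUE)
}
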