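# Genotype input: plain TSV matrix, PLINK-.raw-style dosage text, or VCF.
# All formats are normalised to one tibble of individuals (0/1/2 columns plus
# a binary `phenotype` column) with a `snp_info` attribute. Allele
# orientation is fixed cohort-wide on the pooled sample: any column whose
# counted-allele frequency exceeds 0.5 is flipped to minor-allele counts so
# that case and control correlations are sign-comparable.

#' Read a genotype matrix with phenotypes
#'
#' @param path Input file.
#' @param format `"tsv"` (header + one row per individual, a binary
#'   phenotype column, remaining columns 0/1/2 counts), `"plink-raw"`
#'   (PLINK `--recode A` style: FID IID PAT MAT SEX PHENOTYPE then one
#'   dosage column per SNP; PHENOTYPE coded 1/2 or 0/1, -9 missing), or
#'   `"vcf"` (GT field converted to ALT-allele counts; `./.` becomes
#'   missing; multiallelic records skipped with a message).
#' @param phenotype_file Optional two-column whitespace/tab file
#'   `sample_id status` (status 0/1) used for `"vcf"` (required) or to
#'   override the in-file phenotype; samples are matched by id.
#' @param phenotype_col Name of the phenotype column for `"tsv"` input.
#' @param snp_info Optional data frame with columns `snp` and `gene` used to
#'   annotate scans.
#' @param orient_minor Flip columns so counts refer to the cohort minor
#'   allele (default TRUE).
#' @return A tibble of individuals (`phenotype` + SNP columns, possibly with
#'   `sample_id`), with attribute `snp_info`: a tibble `snp`, `maf`,
#'   `flipped`, and `gene` when provided.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink-raw", "vcf"),
                           phenotype_file = NULL, phenotype_col = "phenotype",
                           snp_info = NULL, orient_minor = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) coassoc_abort("parse_error", paste("file not found:", path))
  out <- switch(format,
    "tsv" = read_genotypes_tsv(path, phenotype_col),
    "plink-raw" = read_genotypes_raw(path),
    "vcf" = read_genotypes_vcf(path)
  )
  if (!is.null(phenotype_file)) {
    ph <- readr::read_table(phenotype_file, col_names = c("sample_id", "status"),
                            show_col_types = FALSE, progress = FALSE,
                            comment = "#")
    if (!"sample_id" %in% names(out)) {
      coassoc_abort("phenotype_error", "input has no sample_id column to match the phenotype file")
    }
    out$phenotype <- ph$status[match(out$sample_id, ph$sample_id)]
  }
  if (is.null(out$phenotype) || !all(out$phenotype %in% c(0, 1), na.rm = TRUE)) {
    coassoc_abort("phenotype_error", "phenotype must be binary 0/1 after decoding")
  }
  snp_cols <- setdiff(names(out), c("sample_id", "phenotype"))
  bad <- snp_cols[vapply(out[snp_cols],
                         function(g) !all(g %in% c(0, 1, 2) | is.na(g)), logical(1))]
  if (length(bad) > 0) {
    coassoc_abort("parse_error",
      sprintf("non-genotype values (outside {0,1,2,NA}) in column(s): %s",
              paste(head(bad, 5), collapse = ", ")))
  }
  info <- tibble(snp = snp_cols,
                 maf = vapply(out[snp_cols], function(g) mean(g, na.rm = TRUE) / 2, numeric(1)),
                 flipped = FALSE)
  if (orient_minor) {
    flip <- info$maf > 0.5
    for (s in info$snp[flip]) out[[s]] <- 2 - out[[s]]
    info$maf[flip] <- 1 - info$maf[flip]
    info$flipped <- flip
  }
  if (!is.null(snp_info)) {
    info <- left_join(info, as_tibble(snp_info), by = "snp")
  }
  attr(out, "snp_info") <- info
  out
}

read_genotypes_tsv <- function(path, phenotype_col) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!phenotype_col %in% names(d)) {
    coassoc_abort("phenotype_error",
      sprintf("phenotype column '%s' not found in TSV", phenotype_col))
  }
  dplyr::rename(d, phenotype = dplyr::all_of(phenotype_col))
}

read_genotypes_raw <- function(path) {
  d <- readr::read_table(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(d))) {
    coassoc_abort("parse_error", "PLINK .raw header must start with FID IID PAT MAT SEX PHENOTYPE")
  }
  ph <- d$PHENOTYPE
  ph[ph == -9] <- NA
  if (all(ph %in% c(1, 2) | is.na(ph))) ph <- ph - 1  # 1/2 -> control/case
  snps <- d[setdiff(names(d), need)]
  # strip the _<counted allele> suffix PLINK appends to SNP ids
  names(snps) <- sub("_[ACGT0-9]+$", "", names(snps))
  dplyr::bind_cols(tibble(sample_id = as.character(d$IID), phenotype = ph), snps)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getALT(vcf), fixed = TRUE)
  if (any(multi)) {
    message(sprintf("skipping %d multiallelic VCF record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  })
  ids <- vcfR::getID(vcf)
  if (any(is.na(ids))) {
    ids[is.na(ids)] <- paste0(vcfR::getCHROM(vcf)[is.na(ids)], ":",
                              vcfR::getPOS(vcf)[is.na(ids)])
  }
  rownames(counts) <- ids
  out <- as_tibble(t(counts))
  dplyr::bind_cols(tibble(sample_id = colnames(counts)), out)
}

#' Write genotype fixtures as plain text
#'
#' `write_genotype_tsv()` writes the individual-by-SNP tibble (with its
#' phenotype column) as TSV; `write_plink_raw()` writes a PLINK
#' `--recode A`-style dosage file. Both echo provenance (`# key: value`
#' comment lines, including the generating scenario when supplied) into the
#' header so fixtures are self-describing.
#'
#' @param data Tibble of individuals as produced by [draw_study()] or
#'   [read_genotypes()].
#' @param path Output file.
#' @param scenario Optional [coassoc_scenario()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(data, path, scenario = NULL) {
  writeLines(provenance_header(scenario), path)
  readr::write_tsv(as_tibble(data), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
write_plink_raw <- function(data, path, scenario = NULL) {
  data <- as_tibble(data)
  snp_cols <- setdiff(names(data), c("sample_id", "phenotype"))
  ids <- if ("sample_id" %in% names(data)) data$sample_id else paste0("ind", seq_len(nrow(data)))
  out <- dplyr::bind_cols(
    tibble(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
           PHENOTYPE = data$phenotype + 1L),
    data[snp_cols]
  )
  writeLines(provenance_header(scenario), path)
  readr::write_delim(out, path, delim = " ", append = TRUE, col_names = TRUE)
  invisible(path)
}

provenance_header <- function(scenario = NULL) {
  h <- c(sprintf("# coassoc %s", as.character(packageVersion("coassoc"))),
         sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(scenario)) {
    h <- c(h, sprintf(
      "# scenario: maf1=%g maf2=%g r=%g beta0=%g beta1=%g beta2=%g beta3=%g n_sample=%d n_population=%d type=%s",
      scenario$maf1, scenario$maf2, scenario$r, scenario$beta0, scenario$beta1,
      scenario$beta2, scenario$beta3, scenario$n_sample, scenario$n_population,
      scenario$coassoc_type))
  }
  h
}

#' Write / read a scenario as a plain key=value config file
#'
#' @param scenario A [coassoc_scenario()].
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a `coassoc_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  keys <- c("maf1", "maf2", "r", "beta0", "beta1", "beta2", "beta3",
            "n_sample", "n_population", "reps", "seed")
  lines <- vapply(keys, function(k) {
    v <- scenario[[k]]
    sprintf("%s=%s", k, if (is.null(v)) "" else format(v, digits = 17))
  }, character(1))
  writeLines(c("# coassoc scenario", lines), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1)),
                   vapply(kv, `[`, character(1), 1))
  num <- function(k, default = NULL) {
    if (!k %in% names(vals) || vals[[k]] == "") return(default)
    as.numeric(vals[[k]])
  }
  coassoc_scenario(
    maf1 = num("maf1", 0.2), maf2 = num("maf2", 0.3), r = num("r", 0),
    beta0 = num("beta0"), beta1 = num("beta1", 0), beta2 = num("beta2", 0),
    beta3 = num("beta3", 0),
    n_sample = num("n_sample", 3000),
    n_population = num("n_population", 2 * num("n_sample", 3000)),
    reps = num("reps", 3000), seed = num("seed")
  )
}
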