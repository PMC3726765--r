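Package: coassoc
Title: Gene-Gene Co-Association Testing for Case-Control GWAS
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-gene co-association in case-control genome-wide
    association data by comparing genotype correlations between cases and
    controls on the Fisher r-to-z scale. Implements the plain Fisher
    z-difference test, a moment-based variant whose variance comes from the
    fourth-moment asymptotic distribution of the sample correlation for
    counting variables, and a fast empirically calibrated variant, together
    with the classical logistic-regression interaction test as a comparator.
    Includes a Gaussian-copula simulator for correlated biallelic genotypes
    under Hardy-Weinberg proportions with logistic case-control phenotypes,
    an exhaustive pairwise scan over TSV/PLINK-raw/VCF input, and scripted
    simulation experiments (type-I error tables, power curves, linkage-
    disequilibrium robustness, multi-cohort false-positive study).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
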