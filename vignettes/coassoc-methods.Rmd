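---
title: "Co-association statistics: models, calibration and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-association statistics: models, calibration and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coassoc)
```

## The testing problem

In a case-control design, two SNPs can contribute to disease beyond their
marginal effects through two channels: a product-term interaction on the
logit scale, and the correlation between the SNPs themselves (pathway
co-membership, LD across linked genes). We call the union *co-association*
and classify conditions by which channel is active: interaction with
independent SNPs (type I), correlation with main effects but no interaction
(type II), both (type III). The product-term logistic LRT only sees the
first channel; the correlation channel shows up instead as a *difference
between the case and control genotype correlations* of the pair, which is
what the package tests.

Why conditioning on disease separates the correlations: with main effects
present, `P(g1, g2 | D = 1) ∝ P(g1, g2) · expit(b0 + b1 g1 + b2 g2)` does
not factorise even when `b3 = 0`, and the distortion differs between cases
and controls whenever the SNPs carry joint effect. Under the null designs
used throughout (no interaction and either independent SNPs or no main
effects) the case and control correlations share one population value and
the z-difference statistics are centred.

## The three z-difference statistics

All three share the numerator `z1 - z0` with `z = atanh(r)` per group and
differ only in the variance estimate:

* `fisher`: `1/(n1-3) + 1/(n0-3)` — Fisher's classical result, exact under
  bivariate normality. Genotypes are counts, not normals: the true null
  variance of `ẑ` drifts upward with correlation, so this test inflates at
  high `r` (visible in the correlated-null table below).
* `wz`: per-group delta-method variance of the sample correlation from
  central joint moments up to order four, divided by `(1 - r²)²` for the z
  scale. For bivariate normal inputs the formula collapses to
  `(1 - r²)²/n`, recovering Fisher's value; for counting variables it is
  the correct asymptotic variance at any correlation. Near `r = 0` the
  bracketed form is numerically unstable (terms in `1/μ11`), so below
  `|r| < 1e-4` the exact zero-correlation limit `μ22/(μ20 μ02)` is used.
* `calib`: keeps the `1/(n-3)` skeleton and multiplies it by
  `f(z̄) = exp(b|z̄| + c z̄²)` of the pooled Fisher z. The motivation is
  purely computational: `wz` needs eight mixed moments per pair per group,
  `calib` needs three correlations, which on exhaustive scans (hundreds of
  thousands of pairs) is the difference between hours and minutes.

Two-sided normal p-values throughout, no continuity correction. Swapping
the case and control labels negates all three statistics and leaves
p-values unchanged; swapping the counted allele at either SNP flips the
sign of `r` in both groups and leaves the magnitudes unchanged (`f` is even
in `z̄` by construction). Both invariances are asserted in the test suite.

Degenerate inputs are refused rather than patched: monomorphic SNPs within
a group have no correlation, and `|r| > 1 - 1e-8` (duplicated SNPs) makes
both `atanh` and the Jacobian blow up, so such pairs carry a classed error
that the scan layer converts into a `skip_reason`. Missing genotypes are
handled pairwise complete-case per SNP pair per group — unbiased under
MCAR, and the simplest rule given that missingness is not modelled here.
Within-dataset MAF below 0.05 is refused by default (overridable with a
warning): the type-I error of these statistics is unstable for rare
variation.

## Calibration of the fast statistic

`f` is fitted once on a simulated corpus: all unordered MAF pairs over
{0.1, ..., 0.5} crossed with target correlations
{0, 0.15, 0.3, 0.45, 0.6, 0.75, 0.9, 0.95} (infeasible combinations
skipped — see the Fréchet bound below), 500 independent pairs of
n = 10000 individuals per grid point, recording
`Var(ẑ) · (n - 3)` (so 1 is the bivariate-normal reference and the factor
is sample-size-free) against the mean ẑ. The shipped artifact
(`inst/extdata/calibration-default.txt`, plain text, seed 101) has 93 grid
points with |z| up to 1.83.

The regression is least squares of `log` relative variance on `|z̄|` and
`z̄²` *through the origin*. The missing intercept is deliberate: at
independence `μ22 = μ20 μ02`, so the relative variance is 1 up to `O(1/n)`
for any counting margins — `f(0) = 1` is a theorem, not a parameter, and
imposing it makes the calibrated statistic coincide with the plain Fisher
test for uncorrelated pairs (its design goal). Fitting an intercept
instead lets lack-of-fit over so wide a correlation span lift `f(0)` to
~1.07, which visibly miscalibrates the many near-independent pairs of a
real scan.

```{r calibration, fig.width = 6, fig.height = 4}
cal <- default_calibration()
cal
tidy(cal)
autoplot(cal)
```

The scatter around the fitted curve is real heterogeneity, not noise: at a
given `z̄` different MAF pairs have different relative variances, and a
univariate `f(z̄)` can only average over them. That residual mis-calibration
is why the calibrated test drifts mildly above nominal at intermediate
correlation in the correlated-null table (measured below ~0.06–0.07 at
r = 0.4, against ~0.05 for `wz`) — the accepted price for the speed. The
model extrapolates beyond |z| = 1.83 with a logged warning rather than an
error, since scans legitimately meet near-duplicate pairs.

Refitting with the same seed reproduces the coefficients bit-for-bit
(`calibrate_coassoc()` or the `coassoc calibrate` CLI subcommand; the
artifact round-trips through a plain-text format).

## The genotype simulator

A SNP with minor allele frequency `p` has HWE genotype probabilities
`((1-p)², 2p(1-p), p²)`; a latent standard normal is cut at the matching
quantiles. A pair shares a latent bivariate normal whose correlation is
solved numerically (one-dimensional Gaussian integrals, inverted with
`uniroot`) so the *genotype-scale* Pearson correlation hits the requested
target. This reproduces the two features that matter for these statistics
— HWE margins and a controllable inter-SNP correlation — while making no
claim to haplotype realism: no recombination maps, no allele-frequency
spectra, no population stratification. Passing tests therefore say the
statistics behave under clean HWE sampling with the stated correlation
structure, not that every real LD pattern is covered.

**Feasibility.** Margins constrain correlations: the comonotone coupling of
`Binom(2, 0.2)` and `Binom(2, 0.3)` has `r ≈ 0.791`, so *no* joint
distribution with those HWE margins reaches `r = 0.8`. The simulator
computes the attainable interval and refuses targets outside it. The
correlated-null table therefore runs its `r = 0.8` row at equal MAFs
0.30/0.30 (feasible up to `r ≈ 1`), keeping "MAFs of roughly 20–30%" while
respecting the bound; all other rows use 0.20/0.30 exactly.

**Disease model and sampling.** Case-control status is Bernoulli with
`logit P(D) = b0 + b1 g1 + b2 g2 + b3 g1 g2`. Published two-SNP designs of
this kind rarely print `b0` or the main-effect sizes, so the package fixes
them once: main effects of `log(1.3)` per allele (an odds ratio in the
middle of the 1.1–1.5 range such studies sweep), and `b0` solved by root
finding so the population prevalence is 0.5 — which makes
sample-irrespective-of-status draws come out near-balanced, the regime the
type-I tables assume. Each replicate generates a population and samples
`n_sample` individuals without replacement irrespective of status; since a
subset of iid draws is iid, the package defaults the population to
`2 * n_sample` rather than 10^5 — the sample law is identical and the
experiments run an order of magnitude faster. Draws with fewer than 50
cases or controls are rejected and redrawn (at most 10 times, warning
each time); at prevalence 0.5 this is a formality.

**LD region.** The LD-robustness study needs "two neighbouring genes in a
strong-LD region". A single AR(1) chain cannot deliver that: with
`rho = 0.9`, SNPs 10–16 steps apart fall to latent correlation 0.35–0.18,
and the two-causal-SNP arm loses its signal. `simulate_ld_region()`
therefore uses two AR(1) blocks (8 + 9 SNPs, `rho = 0.9`) sharing a
regional factor that contributes half the latent variance: adjacent
within-gene SNPs sit near latent 0.95, between-gene pairs near 0.5 —
haplotype-block-like structure with high within-gene and substantial
cross-gene LD. The pure AR(1) generator (`simulate_ld_block()`) remains
available as a primitive.

## The experiments

All drivers are deterministic given `(configuration, seed)` — each cell
derives a sub-seed from the base seed — and report the binomial Monte-Carlo
standard error next to every rejection rate. Comparisons against reference
values in the acceptance tests allow `3·MCSE` plus a 0.015
simulator-mismatch margin, since our generator is not the original
haplotype pipeline of any published table.

* `type1_main_effects()` — uncorrelated null (r = 0, `b3 = 0`) with one or
  two main effects, n = 1000–5000. All four statistics should sit at the
  nominal 0.05; measured cells at 3000 replicates fall within 0.04–0.06.
* `type1_correlation()` — correlated null (no main effects), r = 0.2–0.8 at
  n = 3000/5000. `wz` stays nominal across the sweep; `fisher` inflates
  with r (to ~0.15 by r = 0.8); `calib` runs mildly above nominal at
  intermediate r (~0.06–0.07) and back to nominal at the extremes.
* `power_curves()` — four panels crossing the taxonomy: (a) `b3` sweep at
  r = 0, where all tests climb together and the z-difference tests track
  the LRT within 0.02–0.05; (b) r sweep at `b3 = 0` with main effects,
  where the LRT stays at its nominal level (the model is correctly
  specified with `b3 = 0`) while the z-difference tests gain power with r;
  (c) r sweep at fixed `b3 = 0.2`; (d) `b3` sweep at fixed r = 0.4.
* `ld_effect()` — two arms on the LD region at n = 6000: one causal SNP
  with its LD neighbours tested (rejection stays in the null envelope:
  correlation alone, however strong, carries no joint effect), versus two
  causal SNPs tested through LD proxies (rejection rises well above it,
  e.g. ~0.20 at odds ratio 1.5 versus ~0.05–0.08 in arm one at 600
  replicates).
* `roadmap_fp()` — the staged-design study: a causal correlated pair
  (MAFs 0.31/0.30, r = 0.96, main effects `log(1.3)`) embedded in a null
  background; three independent cohorts (3000/3000/6000) are scanned and a
  non-causal pair counts as a false positive only when it beats the causal
  pair's p-value in *all three*. Desk-scale default is 100 background SNPs
  and 20 replicates (the full design, 1000 x 100, runs behind the CLI's
  `--full` flag); the cross-cohort intersection is reported next to the
  single-cohort rate it shrinks.

Problem sizes in the shipped test-suite and acceptance runs (1000–3000
replicates per cell, populations of `2 * n_sample`) were chosen so a single
desktop core reproduces every table in minutes; the same drivers scale to
the full designs by raising `reps`, `n_population` and `m_background`.

## Numerical choices, in one place

* Degeneracy threshold `|r| > 1 - 1e-8`; moment-form switch at
  `|r| < 1e-4`; copula inversion tolerance `1e-9` on the latent scale;
  feasibility bounds evaluated at latent `±(1 - 1e-6)`.
* IRLS via `glm.fit`: deviance tolerance `1e-8`, 100 iterations.
  Separation is declared on coefficient norm > 10³ *or* fitted
  probabilities pinned within `1e-10` of 0/1 — the latter matters because
  IRLS can meet the deviance tolerance at the boundary with finite
  coefficients, so a norm rule alone never fires.
* Minor-allele orientation is fixed on the pooled sample before splitting
  by status, so case and control correlations are sign-comparable; scan
  output records which columns were flipped.
* Multiple-testing adjustment is `p.adjust` (BH / Bonferroni) on the
  non-missing p-values; the default is raw p-values, matching the
  fixed-threshold reporting conventional in pairwise scans.

## Known limitations

No covariate adjustment (stratified or partial-correlation extensions are
out of scope); rare variants are refused rather than supported; the
simulator's null is exact HWE sampling, so real-data artefacts
(genotyping error, stratification, differential missingness) are outside
what the shipped tests demonstrate; and `calib`'s residual drift above
nominal at intermediate correlation is inherent to any univariate `f(z̄)`
— when exactness matters more than speed, run `wz`.
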