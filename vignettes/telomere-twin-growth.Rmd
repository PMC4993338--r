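---
title: "Modelling longitudinal telomere attrition in twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal telomere attrition in twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twingrowth)
```

## The scientific problem

Leukocyte telomere length (LTL), measured by qPCR as a T/S-ratio (telomere
product over a single-copy reference gene product), declines with age, is
shorter in men than in women, and is partly heritable. Cross-sectional
age–LTL regressions confound cohort and ageing effects, and with only two
or three measurements per person one cannot separate a population-average
trend from individual variation in the *rate* of change. Twin cohorts with
up to five repeated measurements over ~20 years allow both: a latent growth
curve (LGC) mixed model estimates the mean trajectory with a possible
change point, and the twin structure splits individual variation into a
familial part (shared by both members of a pair) and a non-familial,
individual-specific part.

`twingrowth` implements that analysis end to end: a synthetic twin-cohort
generator with the statistical structure the models assume, qPCR
preprocessing (plate batch adjustment, k-SD outlier exclusion, duplicate
CV), an un-weighted 7-SNP genetic risk score (GRS) for shorter LTL,
cross-sectional regression with twin-pair-clustered sandwich standard
errors, the LGC model ladder with maximum-likelihood fitting and
likelihood-ratio comparison, and within-individual change metrics
(telomere "elongation" fractions, loess trend).

## The two-slope latent growth curve model

For individual $i$ of pair $j$ measured at age $t$, write
$B_1(t) = \min(t - c, 0)$ and $B_2(t) = \max(t - c, 0)$ with knot
$c = 69.3$ years (the cohort's median age at the third measurement wave).
The two-slope model is

$$y_{ijt} = \underbrace{\mu_I + \mu_{S1} B_1 + \mu_{S2} B_2 +
\beta_{sex}\,\mathrm{male}_i + \beta_{grs}\,\widetilde{GRS}_i}_{\text{fixed}}
\;+\; \mathbf{a}_j'\mathbf{z}_t + \mathbf{b}_{ij}'\mathbf{z}_t +
\varepsilon_{ijt},$$

with growth basis $\mathbf{z}_t = (1, B_1, B_2)'$, between-pair deviations
$\mathbf{a}_j \sim N(0, \Sigma_B)$ shared by both twins, within-pair
deviations $\mathbf{b}_{ij} \sim N(0, \Sigma_W)$ per individual, and an
occasion-constant residual $\varepsilon \sim N(0, \sigma^2)$. $\Sigma_B$
and $\Sigma_W$ are unstructured over the active growth terms. The ladder
restricts the basis: the intercept-only model drops both slopes, the
one-slope model replaces $(B_1, B_2)$ by the single centered age
$B_1 + B_2$. Sex is coded male = 1 in the longitudinal models, so the
negative sex coefficient means men have lower LTL; the GRS
($\widetilde{GRS}$ = risk-allele count centered on its mean) enters per
allele. Assumptions worth stating plainly: Gaussian errors on the T/S
scale (not log), a residual variance shared across occasions, dropout
ignorable given the model (the data are analysed by ML under
missing-at-random), and no zygosity-specific genetic sharing — the model
decomposes variance into familial vs non-familial, not additive-genetic
vs environmental.

### Estimation

`fit_lgc()` maximizes the exact pairwise multivariate-normal likelihood:
observations of a pair are jointly normal with covariance
$Z_B \Sigma_B Z_B' + \mathrm{blockdiag}(Z_W \Sigma_W Z_W') + \sigma^2 I$,
and pairs are independent. The covariances are parameterized by their
Cholesky factors with log diagonal, making the optimization unconstrained
while keeping both matrices positive semi-definite; the fixed effects are
profiled out by generalized least squares at every variance evaluation, so
the optimizer (`nlminb`, quasi-Newton) works on the $d(d+1) + 1$ variance
parameters only. The per-pair likelihood is evaluated in compiled code.
Estimation is ML, not REML, deliberately: the ladder compares models that
differ in fixed effects, and only ML −2LL differences are valid
chi-square-difference statistics. Starting values are moment-based (OLS
residual variance split 50/25/25 between-pair / within-pair / residual,
slope SDs at 1/20 of the intercept SD); one deterministic perturbed
restart is tried on non-convergence. Boundary solutions (zero variances)
are reported as fitted; the likelihood-ratio test uses the naive
$\chi^2$ reference, as is conventional for this analysis, which is
anticonservative when the constrained parameter sits on the boundary.

Degrees-of-freedom bookkeeping reproduces the standard ladder: with sex,
the intercept-only / one-slope / two-slope models have 5, 10 and 17
parameters ($d$ growth means + covariates, plus $2 \cdot d(d+1)/2$
covariance entries, plus $\sigma^2$); adding a centered GRS gives 18 and a
GRS-by-slope2 interaction 19. AIC is $-2LL + 2k$; for BIC the sample size
is the number of pairs by default (the subject count, mirroring mixed-model
software), configurable to individuals or observations. Published
model-comparison tables for this design are internally inconsistent about
the AIC convention, so AIC/BIC here are computed by the standard formulas
only and model selection in the package rests on the likelihood-ratio
ladder.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions as defaults: 318 same-sex
pairs (636 individuals, 58.5% female, 36% MZ), baseline age
$N(68.9, 9.7^2)$ truncated at 50, occasion gaps 4.4/2.6/2.2/2.2 years
(successive mean-age differences between waves), and monotone retention
1, 0.689, 0.689, 0.543, 0.354, chosen so the expected per-occasion sample
counts decline as 636, 438, 302, 164, 58 (total 1598, 47% of individuals
with ≥3 measurements). Fixed effects default to the published two-slope
estimates (intercept 0.7287, slopes −0.0012 / −0.0021 per year, sex
−0.0409, GRS −0.011 per allele). The residual SD of 0.049 makes the
within-person measurement CV ≈ 7% at the mean T/S of 0.70, matching the
reported qPCR duplicate CV (6.98%); plate effects are additive Gaussian
(SD 0.02 across 20 plates, round-robin assignment within occasion).

The random-effect covariances are *provisional*: the source study's full
variance-component tables are not publicly printed, so defaults were set
once from the qualitative description — intercept variance split equally
between the familial and non-familial level (SD 0.108 each, which together
with the other terms reproduces the pooled cross-sectional SD ≈ 0.17),
slope variation placed mostly at the within-pair level and larger before
the knot than after (within-pair slope SDs 0.007 and 0.004/year; small
between-pair slope SDs 0.002 and 0.0015), zero correlations. They are
fully configurable and should be treated as one plausible calibration, not
an estimate. Risk-allele frequencies default to 0.6 per SNP so the mean
GRS is ≈ 8.4 as observed; with seven equal-frequency, LD-free SNPs the
simulated GRS SD (≈1.8) is larger than the observed 1.43 — real loci have
unequal frequencies. Since the GRS is centered before modelling, this
affects only the spread of the score, not the recovery targets.

Features of real data the generator does not emulate: age- or
health-dependent (informative) dropout, zygosity-specific genetic
sharing, lymphocyte-subpopulation dynamics behind apparent elongation,
assay drift between waves, and twins attending different waves (simulated
twins share measurement ages). Passing recovery tests therefore show the
estimators are consistent and approximately unbiased *under the assumed
model*, not that the model is right for any particular cohort.

`simulate_duplicates()` multiplies each sample by
$1 + s z$, $z \sim N(0,1)$, with $s = \mathrm{CV}\sqrt{\pi/2}$: the
$\sqrt{\pi/2}$ factor undoes the downward bias of a two-replicate SD, so
the expected duplicate CV reported by `compute_cv()` equals the configured
value.

## Preprocessing choices

Batch adjustment regresses raw T/S on plate indicators and adds back the
grand mean; afterwards every plate mean equals the grand mean exactly, and
the operation is idempotent. It is fitted on the full sample *before*
outlier exclusion, following the order in which the analysis is described.
Outlier screening is single-pass (mean and SD from the pre-exclusion data,
k = 4 SDs by default), overall for the cross-sectional set and within
closed-open decade bands [50,60), [60,70), [70,80), [80,∞) for the
longitudinal set; the source text does not state whether its exclusion SDs
were computed before or after batch adjustment, and this package applies
them after (flagged here as a declared choice). The cross-sectional
dataset is each individual's first available measurement. Sex coding
differs by convention between analyses — female = 1 cross-sectionally
(positive coefficient for women's longer LTL), male = 1 longitudinally —
each documented where used.

The cluster sandwich uses the CR1-style factor
$\frac{G}{G-1}\frac{N-1}{N-p}$ with a $t(G-1)$ reference; the exact
small-sample convention of the survey-regression software behind the
published cross-sectional numbers is not printed, so the factor is
configurable (`ssc = "CR0"` for the bare sandwich) and numeric equality
with that software is not claimed.

## Change metrics

`pairwise_deltas()` emits all $m(m-1)/2$ within-individual occasion pairs;
`elongation_fraction()` is the percent of strictly positive deltas (ties
count as non-elongation — a measure-zero event under the continuous
model), optionally stratified by gap rounded to whole years. With the
default calibration (true decline ≈ 0.002/year vs. duplicate-level noise
of ≈ 0.05) the simulated elongation fraction lands in the mid-40s —
demonstrating that measurement noise alone produces apparent elongation at
roughly the published rate. `loess_smooth()` is a tricube-weighted local
*linear* smoother with span-nearest-neighbour bandwidth (span 0.75 by
default, neither stated in the source; degree 1 because the trend of
interest is locally linear), validated against the reference loess
implementation.

## Numerical choices and degenerate inputs

* Non-positive-definite covariance inputs to `neg2_loglik()` return
  `+Inf` with a warning (optimizer-safe) rather than erroring.
* The generator rejects non-PSD covariance configurations and retention
  vectors shorter than the occasion list.
* Plates with a single observation get residual zero; records with
  missing raw values are skipped with a warning.
* Age bands with fewer than two records are left unscreened (SD
  undefined) with a message.
* `fit_lgc()` reports `converged = FALSE` (with optimizer diagnostics)
  instead of failing; a fuller model fitting slightly worse than its
  reduced version beyond a 10^-3 tolerance raises an explicit
  optimizer-failure error in `likelihood_ratio_test()`.
* Fits are invariant to shifting all ages and the centering age by a
  constant; sensitivity analyses (centering ±5 years, zygosity subsets)
  are config options, not separate code paths.

## Problem sizes used in the shipped checks

The package's replication experiments use 50 simulated cohorts of 300
pairs for the longitudinal recovery (mean ML estimates of the intercept,
post-knot slope and sex effect, and Wald-CI coverage) and 50 cohorts of
318 pairs for the cross-sectional recovery, sizes chosen to keep the
Monte-Carlo standard error of each replicate mean well below the
published precision of the corresponding estimate while remaining
comfortably runnable on a laptop. Oracle-equivalence checks (pairwise vs.
joint-matrix likelihood) use cohorts of ≤10 pairs where the brute-force
joint covariance is cheap to assemble.

## Known limitations

* The risk-allele map ships with placeholder alleles; real use requires
  the effect alleles of the source GWAS.
* Variance-component defaults of the generator are a calibration, not
  published values (see above).
* The LRT at variance boundaries is anticonservative (no mixture
  correction), matching common practice for this analysis.
* No SEM-style occasion-specific loadings, quadratic growth, ACE
  decomposition, or generalized estimating equations.

## A worked run

```{r, eval = FALSE}
cfg <- read_run_config(system.file("extdata", "satsa_replica.yaml",
                                   package = "twingrowth"))
res <- run_pipeline(cfg, "satsa_replica_run")
res$ladder
```

This writes the cohort tables, preprocessing and GRS summaries, the
cross-sectional coefficient table, the model-comparison ladder, fixed and
random effects of the two-slope model, the elongation summary and
predicted male/female trajectories, plus a log of the seed and settings,
into the output directory; rerunning with the same seed reproduces every
file byte for byte.
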