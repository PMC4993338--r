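#' Configuration for the synthetic twin-cohort generator
#'
#' Builds the full parameter set that [simulate_cohort()] consumes. The
#' defaults reproduce the structure of a Swedish twin study of ageing in
#' which leukocyte telomere length (LTL, a qPCR T/S-ratio) was measured on
#' up to five occasions over about twenty years: 318 same-sex twin pairs
#' (636 individuals), baseline age drawn from N(68.9, 9.7^2) truncated at 50
#' years, monotone attrition calibrated so expected per-occasion sample
#' counts decline as 636, 438, 302, 164, 58, and a piecewise-linear mean
#' trajectory with a knot at 69.3 years (slopes -0.0012 and -0.0021
#' T/S-ratio per year), a male deficit of 0.0409 T/S-ratio, and a
#' per-risk-allele deficit of 0.011 T/S-ratio.
#'
#' Random variation has four sources: between-pair growth deviations (shared
#' by both twins; the familial component), within-pair growth deviations
#' (one per individual; the non-familial component), additive Gaussian plate
#' batch effects, and an occasion-level Gaussian residual whose default SD
#' of 0.049 gives a coefficient of variation of about 7% at the mean
#' T/S-ratio of 0.70. Intercept variance is split equally between the
#' between- and within-pair levels, and slope variation is placed mostly at
#' the within-pair level with more variation before the knot than after it.
#'
#' @param n_pairs Number of same-sex twin pairs.
#' @param prop_mz Proportion of pairs that are monozygotic.
#' @param prop_female_pairs Proportion of pairs that are female.
#' @param baseline_age_mean,baseline_age_sd Mean and SD (years) of the
#'   baseline-age distribution before truncation.
#' @param min_age Lower truncation bound for baseline age (years).
#' @param occasion_gaps Years between successive measurement occasions.
#' @param retention Per-occasion retention probabilities; element k is the
#'   probability of contributing occasion k given occasion k-1 was
#'   contributed (element 1 is the probability of entering at all). Must be
#'   at least as long as the number of occasions.
#' @param fixed_effects Named list with elements `intercept`, `slope1`,
#'   `slope2` (T/S-ratio per year before/after the knot), `sex_effect`
#'   (T/S-ratio, male = 1 coding, so negative means men lower) and
#'   `grs_effect` (T/S-ratio per centered risk allele).
#' @param centering_age Knot/centering age in years.
#' @param between_pair_cov,within_pair_cov 3x3 symmetric positive
#'   semi-definite covariance matrices of the (intercept, slope1, slope2)
#'   random deviations at pair and individual level.
#' @param residual_sd Occasion-level residual SD (T/S-ratio).
#' @param plate_count Number of qPCR plates; samples are assigned
#'   round-robin within occasion.
#' @param plate_effect_sd SD of the additive Gaussian plate effect.
#' @param duplicate_cv Target coefficient of variation of simulated qPCR
#'   duplicate pairs (fraction, e.g. 0.0698).
#' @param allele_freqs Risk-allele frequencies of the 7 LTL SNPs.
#' @param seed Integer seed; may be overridden in [simulate_cohort()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [cross_sectional_config()] for the single-slope profile used in
#'   cross-sectional recovery experiments.
#' @export
#' @examples
#' cfg <- sim_config(n_pairs = 20, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' nrow(cohort$individuals)
sim_config <- function(n_pairs = 318,
                       prop_mz = 84 / 236,
                       prop_female_pairs = 0.585,
                       baseline_age_mean = 68.9,
                       baseline_age_sd = 9.7,
                       min_age = 50,
                       occasion_gaps = c(4.4, 2.6, 2.2, 2.2),
                       retention = c(1, 438 / 636, 302 / 438, 164 / 302, 58 / 164),
                       fixed_effects = list(intercept = 0.7287,
                                            slope1 = -0.0012,
                                            slope2 = -0.0021,
                                            sex_effect = -0.0409,
                                            grs_effect = -0.011),
                       centering_age = 69.3,
                       between_pair_cov = diag(c(0.108, 0.002, 0.0015)^2),
                       within_pair_cov = diag(c(0.108, 0.007, 0.004)^2),
                       residual_sd = 0.049,
                       plate_count = 20,
                       plate_effect_sd = 0.02,
                       duplicate_cv = 0.0698,
                       allele_freqs = rep(0.6, 7),
                       seed = NULL) {
  cfg <- list(n_pairs = n_pairs, prop_mz = prop_mz,
              prop_female_pairs = prop_female_pairs,
              baseline_age_mean = baseline_age_mean,
              baseline_age_sd = baseline_age_sd, min_age = min_age,
              occasion_gaps = occasion_gaps, retention = retention,
              fixed_effects = fixed_effects, centering_age = centering_age,
              between_pair_cov = between_pair_cov,
              within_pair_cov = within_pair_cov, residual_sd = residual_sd,
              plate_count = plate_count, plate_effect_sd = plate_effect_sd,
              duplicate_cv = duplicate_cv, allele_freqs = allele_freqs,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Generator profile for cross-sectional recovery experiments
#'
#' Same cohort structure as [sim_config()] but with a single linear age
#' slope of -0.0022 T/S-ratio per year on both sides of the knot and a sex
#' effect of magnitude 0.0499 (men lower), matching the generating values
#' used when checking that the cluster-robust cross-sectional regression
#' recovers its coefficients.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` object.
#' @export
cross_sectional_config <- function(...) {
  args <- list(...)
  fe <- list(intercept = 0.7287, slope1 = -0.0022, slope2 = -0.0022,
             sex_effect = -0.0499, grs_effect = -0.011)
  if (!is.null(args$fixed_effects)) {
    fe[names(args$fixed_effects)] <- args$fixed_effects
  }
  args$fixed_effects <- fe
  do.call(sim_config, args)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_pairs >= 1, cfg$prop_mz >= 0, cfg$prop_mz <= 1,
            cfg$prop_female_pairs >= 0, cfg$prop_female_pairs <= 1)
  if (any(cfg$occasion_gaps <= 0)) {
    stop("occasion_gaps must be strictly positive")
  }
  n_occ <- length(cfg$occasion_gaps) + 1L
  if (length(cfg$retention) < n_occ) {
    stop("retention must have one probability per occasion (need ",
         n_occ, ", got ", length(cfg$retention), ")")
  }
  if (any(cfg$retention < 0 | cfg$retention > 1)) {
    stop("retention probabilities must lie in [0, 1]")
  }
  for (nm in c("between_pair_cov", "within_pair_cov")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || !isSymmetric(m, tol = 1e-8)) {
      stop(nm, " must be a symmetric 3x3 matrix")
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop(nm, " must be positive semi-definite")
    }
  }
  sds <- c(cfg$baseline_age_sd, cfg$residual_sd, cfg$plate_effect_sd,
           cfg$duplicate_cv)
  if (any(sds < 0)) stop("SD and CV parameters must be non-negative")
  req <- c("intercept", "slope1", "slope2", "sex_effect", "grs_effect")
  if (!all(req %in% names(cfg$fixed_effects))) {
    stop("fixed_effects must contain: ", paste(req, collapse = ", "))
  }
  if (length(cfg$allele_freqs) != 7 ||
      any(cfg$allele_freqs <= 0 | cfg$allele_freqs >= 1)) {
    stop("allele_freqs must be 7 frequencies in (0, 1)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n_occ <- length(x$occasion_gaps) + 1L
  cat("Twin-cohort simulation configuration\n")
  cat(sprintf("  %d pairs (%.0f%% MZ, %.0f%% female), up to %d occasions\n",
              x$n_pairs, 100 * x$prop_mz, 100 * x$prop_female_pairs, n_occ))
  fe <- x$fixed_effects
  cat(sprintf("  trajectory: %.4f %+.4f*B1 %+.4f*B2 (knot %.1f y), sex %+.4f, grs %+.4f\n",
              fe$intercept, fe$slope1, fe$slope2, x$centering_age,
              fe$sex_effect, fe$grs_effect))
  cat(sprintf("  residual sd %.3f, plate sd %.3f on %d plates, duplicate CV %.2f%%\n",
              x$residual_sd, x$plate_effect_sd, x$plate_count,
              100 * x$duplicate_cv))
  invisible(x)
}
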