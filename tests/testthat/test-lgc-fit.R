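test_that("one observation, intercept-only model reduces to a scalar normal", {
  m <- data.frame(individual_id = "a_1", pair_id = "a", occasion = 1,
                  age_at_draw = 72, ts_adjusted = 0.64)
  ind <- data.frame(individual_id = "a_1", pair_id = "a", sex = "female")
  sp <- lgc_spec("intercept", covariates = "sex")
  d <- lgc_data(sp, m, ind)
  params <- list(fixed = c(intercept = 0.7, sex = -0.04),
                 between_pair_cov = matrix(0.01),
                 within_pair_cov = matrix(0.02),
                 residual_var = 0.0025)
  v_tot <- 0.01 + 0.02 + 0.0025
  closed <- -2 * dnorm(0.64, 0.7, sqrt(v_tot), log = TRUE)
  expect_equal(neg2_loglik(params, d), closed, tolerance = 1e-12)
})

test_that("pairwise likelihood equals the full joint multivariate normal", {
  specs <- list(lgc_spec("intercept", covariates = "sex"),
                lgc_spec(c("intercept", "slope1"), covariates = "sex"),
                lgc_spec(c("intercept", "slope1", "slope2"),
                         covariates = "sex"))
  co <- small_cohort(n_pairs = 8, seed = 71)
  set.seed(42)
  for (sp in specs) {
    d <- lgc_data(sp, co$measurements, co$individuals)
    for (rep in 1:3) {
      params <- rand_params(sp)
      v1 <- neg2_loglik(params, d)
      v2 <- brute_force_m2ll(params, d)
      expect_equal(v1, v2, tolerance = 1e-8)
    }
  }
})

test_that("non-positive-definite covariance parameters give +Inf, not an error", {
  co <- small_cohort(n_pairs = 4, seed = 72)
  sp <- lgc_spec()
  d <- lgc_data(sp, co$measurements, co$individuals)
  bad <- list(fixed = c(intercept = 0.7, slope1 = 0, slope2 = 0, sex = 0),
              between_pair_cov = diag(c(-0.05, 0.01, 0.01)),
              within_pair_cov = diag(3) * 0.01, residual_var = 0)
  expect_warning(v <- neg2_loglik(bad, d), "non-positive-definite|Inf")
  expect_equal(v, Inf)
})

test_that("near-noise-free data recovers the generating fixed effects", {
  cfg <- sim_config(n_pairs = 60, seed = 14, retention = rep(1, 5),
                    between_pair_cov = matrix(0, 3, 3),
                    within_pair_cov = matrix(0, 3, 3),
                    residual_sd = 0.001, plate_effect_sd = 0,
                    fixed_effects = list(intercept = 0.73, slope1 = -0.0015,
                                         slope2 = -0.0025, sex_effect = -0.04,
                                         grs_effect = 0))
  co <- simulate_cohort(cfg)
  f <- fit_lgc(lgc_spec(), co$measurements, co$individuals,
               response = "ts_raw")
  expect_equal(unname(coef(f)), c(0.73, -0.0015, -0.0025, -0.04),
               tolerance = 5e-3)
  expect_lt(max(abs(coef(f) - c(0.73, -0.0015, -0.0025, -0.04))), 2e-4)
})

test_that("maximum likelihood agrees with an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  co <- simulate_cohort(sim_config(n_pairs = 150, retention = rep(1, 5),
                                   seed = 11))
  m <- adjust_batch(co$measurements)
  dat <- merge(m, co$individuals[, c("individual_id", "sex")],
               by = "individual_id")
  ab <- age_basis(dat$age_at_draw)
  dat$b1 <- ab[, 1]; dat$b2 <- ab[, 2]
  dat$male <- as.numeric(dat$sex == "male")
  lf <- lme4::lmer(
    ts_adjusted ~ b1 + b2 + male + (1 + b1 + b2 | pair_id) +
      (1 + b1 + b2 | individual_id),
    data = dat, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                calc.derivs = FALSE))
  f <- fit_lgc(lgc_spec(), m, co$individuals)
  # same optimum found by both implementations
  expect_equal(f$minus2ll, deviance(lf), tolerance = 1e-6)
  expect_equal(unname(coef(f)), unname(lme4::fixef(lf)), tolerance = 1e-4)
  # likelihood evaluation agrees at the oracle's own estimates
  vc <- lme4::VarCorr(lf)
  at_lmer <- list(
    fixed = setNames(lme4::fixef(lf), c("intercept", "slope1", "slope2", "sex")),
    between_pair_cov = matrix(vc$pair_id, 3, 3),
    within_pair_cov = matrix(vc$individual_id, 3, 3),
    residual_var = stats::sigma(lf)^2)
  d <- lgc_data(lgc_spec(), m, co$individuals)
  expect_equal(neg2_loglik(at_lmer, d), deviance(lf), tolerance = 1e-8)
})

test_that("fuller nested models never fit worse, and AIC follows -2LL", {
  co <- small_cohort(n_pairs = 100, seed = 44)
  m1 <- fit_lgc(lgc_spec("intercept", covariates = "sex"),
                co$measurements, co$individuals)
  m2 <- fit_lgc(lgc_spec(c("intercept", "slope1"), covariates = "sex"),
                co$measurements, co$individuals)
  m3 <- fit_lgc(lgc_spec(), co$measurements, co$individuals)
  expect_gte(m1$minus2ll - m2$minus2ll, -1e-3)
  expect_gte(m2$minus2ll - m3$minus2ll, -1e-3)
  for (f in list(m1, m2, m3)) {
    expect_equal(f$aic, f$minus2ll + 2 * f$parameter_count)
    expect_equal(f$bic, f$minus2ll + log(f$n_pairs) * f$parameter_count)
  }
  expect_equal(c(m1$parameter_count, m2$parameter_count, m3$parameter_count),
               c(5L, 10L, 17L))

  lrt <- likelihood_ratio_test(m1, m2)
  expect_equal(lrt$df, 5)
  expect_equal(lrt$delta_minus2ll, m1$minus2ll - m2$minus2ll)
  expect_error(likelihood_ratio_test(m3, m2), "not nested")
  same <- likelihood_ratio_test(m3, m3)
  expect_equal(same$delta_minus2ll, 0)
  expect_equal(same$p, 1)

  tab <- compare_models(list(intercept = m1, one_slope = m2, two_slope = m3))
  expect_equal(tab$parms, c(5L, 10L, 17L))
  expect_equal(tab$delta_m2ll[2], m1$minus2ll - m2$minus2ll)
})

test_that("the fit is invariant to shifting ages and knot together", {
  co <- small_cohort(n_pairs = 50, seed = 55)
  f1 <- fit_lgc(lgc_spec(), co$measurements, co$individuals)
  m_shift <- co$measurements
  m_shift$age_at_draw <- m_shift$age_at_draw + 7
  f2 <- fit_lgc(lgc_spec(centering_age = 69.3 + 7), m_shift, co$individuals)
  expect_equal(f1$minus2ll, f2$minus2ll, tolerance = 1e-8)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("chi-square difference arithmetic", {
  out <- chisq_diff_test(-100, -110.5, 5, 10)
  expect_equal(out$delta_minus2ll, 10.5)
  expect_equal(out$df, 5)
  expect_equal(out$p, pchisq(10.5, 5, lower.tail = FALSE))
  expect_error(chisq_diff_test(-100, -110, 10, 5), "fewer parameters")
})

test_that("predicted trajectories behave like the fitted fixed effects", {
  co <- small_cohort(n_pairs = 80, seed = 66)
  f <- fit_lgc(lgc_spec(), co$measurements, co$individuals)
  at_knot <- predict_trajectory(f, 69.3, sex = "female")
  expect_equal(at_knot$ts_predicted, unname(coef(f)["intercept"]))
  ages <- seq(55, 90, by = 5)
  fem <- predict_trajectory(f, ages, sex = "female")
  mal <- predict_trajectory(f, ages, sex = "male")
  # parallel curves: constant male-female difference = sex coefficient
  expect_equal(mal$ts_predicted - fem$ts_predicted,
               rep(unname(coef(f)["sex"]), length(ages)))
  # piecewise linear with the configured slopes
  left <- predict_trajectory(f, c(60, 61), sex = "female")
  right <- predict_trajectory(f, c(80, 81), sex = "female")
  expect_equal(diff(left$ts_predicted), unname(coef(f)["slope1"]))
  expect_equal(diff(right$ts_predicted), unname(coef(f)["slope2"]))
})

test_that("a GRS covariate shifts predictions by its fitted effect per allele", {
  co <- small_cohort(n_pairs = 80, seed = 67)
  grs <- compute_grs(co$genotypes)
  sp <- lgc_spec(covariates = c("sex", "grs"))
  f <- fit_lgc(sp, co$measurements, co$individuals, grs = grs)
  p0 <- predict_trajectory(f, c(60, 75), sex = "female", grs = 0)
  p1 <- predict_trajectory(f, c(60, 75), sex = "female", grs = 1)
  expect_equal(p1$ts_predicted - p0$ts_predicted,
               rep(unname(coef(f)["grs"]), 2))
  expect_equal(f$parameter_count, 18L)
})

test_that("rows with missing covariates are dropped with a message", {
  co <- small_cohort(n_pairs = 30, seed = 68)
  grs <- compute_grs(co$genotypes)
  grs[1:4] <- NA
  sp <- lgc_spec(covariates = c("sex", "grs"))
  expect_message(d <- lgc_data(sp, co$measurements, co$individuals, grs = grs),
                 "dropped")
  expect_lt(d$n_individuals, 60)
})
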