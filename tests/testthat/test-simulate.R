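test_that("identical config and seed give identical cohorts", {
  cfg <- sim_config(n_pairs = 25)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$genotypes, b$genotypes)
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("cohort structure: same-sex pairs, two per pair, increasing ages", {
  co <- small_cohort()
  ind <- co$individuals
  expect_true(all(table(ind$pair_id) == 2))
  by_pair <- split(ind, ind$pair_id)
  expect_true(all(vapply(by_pair, function(p) length(unique(p$sex)) == 1, TRUE)))
  expect_true(all(vapply(by_pair, function(p) length(unique(p$zygosity)) == 1, TRUE)))
  expect_true(all(ind$baseline_age >= 50))
  m <- co$measurements
  expect_true(all(m$ts_raw > 0))
  ok <- tapply(m$age_at_draw, m$individual_id, function(a) all(diff(a) > 0))
  expect_true(all(ok))
})

test_that("noise-free cohort lies exactly on the deterministic piecewise line", {
  co <- simulate_cohort(noise_free_config())
  expect_equal(co$measurements$ts_raw, expected_trajectory(co), tolerance = 1e-12)
})

test_that("twins share the between-pair deviation", {
  # within-pair and residual noise off: twin trajectories must coincide
  cfg <- sim_config(n_pairs = 40, seed = 3, retention = rep(1, 5),
                    within_pair_cov = matrix(0, 3, 3), residual_sd = 0,
                    plate_effect_sd = 0,
                    fixed_effects = list(intercept = 0.73, slope1 = -0.001,
                                         slope2 = -0.002, sex_effect = -0.04,
                                         grs_effect = 0))
  co <- simulate_cohort(cfg)
  m <- co$measurements
  wide <- split(m$ts_raw, m$individual_id)
  pair_of <- function(id) sub("_[12]$", "", id)
  ids <- names(wide)
  for (p in unique(pair_of(ids))) {
    two <- wide[pair_of(ids) == p]
    expect_equal(two[[1]], two[[2]], tolerance = 1e-12)
  }
})

test_that("full retention gives every individual all occasions", {
  co <- simulate_cohort(sim_config(n_pairs = 30, retention = rep(1, 5),
                                   seed = 5))
  counts <- table(co$measurements$individual_id)
  expect_true(all(counts == 5))
  expect_equal(length(counts), 60)
})

test_that("per-occasion counts track the configured retention ladder", {
  cfg <- sim_config(n_pairs = 2000, seed = 17)
  co <- simulate_cohort(cfg)
  occ <- table(factor(co$measurements$occasion, levels = 1:5))
  expected <- 4000 * cumprod(cfg$retention)
  # per-occasion proportions of the Table-2-style ladder 636:438:302:164:58
  expect_lt(max(abs(as.numeric(occ) - expected) / 4000), 0.02)
})

test_that("pooled adjusted T/S mean and SD sit near 0.70 and 0.17 at defaults", {
  stats <- sapply(1:4, function(s) {
    m <- adjust_batch(simulate_cohort(sim_config(seed = 400 + s))$measurements)
    c(mean(m$ts_adjusted), sd(m$ts_adjusted))
  })
  expect_lt(abs(mean(stats[1, ]) - 0.70), 0.015)
  expect_lt(abs(mean(stats[2, ]) - 0.17), 0.015)
})

test_that("simulated random-effect variance matches the configured covariance", {
  # residual, plate and slope variation off: the individual deviation from
  # the fixed trajectory is a_j + b_ij at every occasion
  sb <- 0.012; sw <- 0.009
  cfg <- sim_config(n_pairs = 3000, seed = 23, retention = c(1, 1, 1, 1, 1),
                    between_pair_cov = diag(c(sb, 0, 0)),
                    within_pair_cov = diag(c(sw, 0, 0)),
                    residual_sd = 0, plate_effect_sd = 0)
  co <- simulate_cohort(cfg)
  dev <- co$measurements$ts_raw - expected_trajectory(co)
  ind_dev <- tapply(dev, co$measurements$individual_id, mean)
  ids <- names(ind_dev)
  pair <- sub("_[12]$", "", ids)
  v_tot <- var(ind_dev)
  twin1 <- ind_dev[match(paste0(unique(pair), "_1"), ids)]
  twin2 <- ind_dev[match(paste0(unique(pair), "_2"), ids)]
  cov_twin <- cov(twin1, twin2)
  tol <- 3 * (sb + sw) / sqrt(3000)
  expect_equal(v_tot, sb + sw, tolerance = tol / (sb + sw))
  expect_equal(cov_twin, sb, tolerance = 3 * tol / sb / sqrt(2))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(between_pair_cov = diag(c(-1, 1, 1))), "semi-definite")
  expect_error(sim_config(retention = c(1, 0.5)), "retention")
  expect_error(sim_config(retention = c(1, 0.5, 0.5, 1.2, 0.4)), "\\[0, 1\\]")
  expect_error(sim_config(occasion_gaps = c(2, -1, 2, 2)), "positive")
  expect_error(sim_config(residual_sd = -0.1), "non-negative")
  expect_error(sim_config(allele_freqs = rep(0.5, 6)), "7 frequencies")
  expect_error(simulate_cohort(sim_config()), "seed")
})

test_that("duplicate simulation reproduces the requested assay CV", {
  co <- small_cohort(n_pairs = 40, seed = 31)
  m0 <- co$measurements
  set.seed(1)
  m <- simulate_duplicates(m0, 0)
  expect_equal(m$dup1, m$ts_raw)
  expect_equal(m$dup2, m$ts_raw)

  big <- m0[rep(seq_len(nrow(m0)), 40), ]
  set.seed(2)
  big <- simulate_duplicates(big, 0.0698)
  expect_equal(compute_cv(big), 6.98, tolerance = 0.03)

  # single sample at 1.0: duplicate CV distributed around 0.0698; oracle is
  # a direct Monte-Carlo of the replicate noise law
  one <- data.frame(ts_raw = rep(1, 5000))
  set.seed(3)
  one <- simulate_duplicates(one, 0.0698)
  cv_obs <- abs(one$dup1 - one$dup2) / sqrt(2) / ((one$dup1 + one$dup2) / 2)
  set.seed(4)
  s <- 0.0698 * sqrt(pi / 2)
  r1 <- 1 + s * rnorm(5000); r2 <- 1 + s * rnorm(5000)
  cv_mc <- abs(r1 - r2) / sqrt(2) / ((r1 + r2) / 2)
  expect_equal(mean(cv_obs), mean(cv_mc), tolerance = 0.05)
  expect_equal(mean(cv_obs), 0.0698, tolerance = 0.03)
})

test_that("cohort CSV round-trip preserves the tables", {
  co <- small_cohort(n_pairs = 10, seed = 77)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$individuals, co$individuals)
  expect_equal(back$measurements, co$measurements, tolerance = 1e-12)
  expect_equal(back$genotypes, co$genotypes)
})
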