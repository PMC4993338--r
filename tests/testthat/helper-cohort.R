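# Shared fixtures: all cohorts are generated in code at test time.

# small default cohort, batch-adjusted, cached per session
small_cohort <- local({
  memo <- new.env()
  function(n_pairs = 60, seed = 101, ...) {
    key <- paste(n_pairs, seed, ...)
    if (is.null(memo[[key]])) {
      co <- simulate_cohort(sim_config(n_pairs = n_pairs, seed = seed, ...))
      co$measurements <- adjust_batch(co$measurements)
      memo[[key]] <- co
    }
    memo[[key]]
  }
})

# a noise-free configuration: deterministic piecewise trajectories
noise_free_config <- function(n_pairs = 30, seed = 7, ...) {
  sim_config(n_pairs = n_pairs, seed = seed,
             between_pair_cov = matrix(0, 3, 3),
             within_pair_cov = matrix(0, 3, 3),
             residual_sd = 0, plate_effect_sd = 0, ...)
}

# deterministic expected mean trajectory for a cohort under its config
expected_trajectory <- function(cohort) {
  cfg <- attr(cohort, "config")
  fe <- cfg$fixed_effects
  m <- cohort$measurements
  ind <- cohort$individuals
  male <- as.numeric(ind$sex[match(m$individual_id, ind$individual_id)] == "male")
  grs <- rowSums(cohort$genotypes[, -1])
  grs_c <- grs - mean(grs)
  B <- age_basis(m$age_at_draw, cfg$centering_age)
  fe$intercept + fe$slope1 * B[, 1] + fe$slope2 * B[, 2] +
    fe$sex_effect * male +
    fe$grs_effect * grs_c[match(m$individual_id, cohort$genotypes$individual_id)]
}

# random (valid) parameter draws for likelihood-identity checks
rand_params <- function(spec, scale = 1) {
  d <- length(spec$growth)
  mk <- function() {
    L <- matrix(0, d, d)
    L[lower.tri(L, diag = TRUE)] <- rnorm(d * (d + 1) / 2, 0, 0.05 * scale)
    diag(L) <- abs(diag(L)) + 0.02
    tcrossprod(L)
  }
  terms <- twingrowth:::spec_fixed_terms(spec)
  fixed <- setNames(rnorm(length(terms), 0, 0.3), terms)
  fixed["intercept"] <- 0.7
  list(fixed = fixed, between_pair_cov = mk(), within_pair_cov = mk(),
       residual_var = runif(1, 0.001, 0.01))
}

# brute-force joint multivariate-normal -2 log-likelihood over ALL
# observations at once (independent of the per-pair implementation)
brute_force_m2ll <- function(params, data) {
  df <- data$frame
  n <- nrow(df)
  spec <- data$spec
  two_slope <- all(c("slope1", "slope2") %in% spec$growth)
  B <- age_basis(df$age_at_draw, spec$centering_age)
  basis <- cbind(intercept = rep(1, n),
                 slope1 = if (two_slope) B[, 1] else B[, 1] + B[, 2],
                 slope2 = B[, 2])[, spec$growth, drop = FALSE]
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (df$pair_id[i] == df$pair_id[j]) {
      V[i, j] <- V[i, j] +
        basis[i, ] %*% params$between_pair_cov %*% basis[j, ]
    }
    if (df$individual_id[i] == df$individual_id[j]) {
      V[i, j] <- V[i, j] +
        basis[i, ] %*% params$within_pair_cov %*% basis[j, ]
    }
    if (i == j) V[i, j] <- V[i, j] + params$residual_var
  }
  X <- data$X
  r <- data$y - as.numeric(X %*% params$fixed[colnames(X)])
  as.numeric(n * log(2 * pi) + determinant(V)$modulus +
               t(r) %*% solve(V) %*% r)
}
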