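# Replicate simulation studies shared by the recovery and coverage tests.
# Computed once per session and cached.

lgc_replicates <- local({
  memo <- new.env()
  function(n_rep = 50, n_pairs = 300) {
    key <- paste0("r", n_rep, "_", n_pairs)
    if (is.null(memo[[key]])) {
      truth <- c(intercept = 0.7287, slope1 = -0.0012, slope2 = -0.0021,
                 sex = -0.0409)
      memo[[key]] <- t(vapply(seq_len(n_rep), function(r) {
        co <- simulate_cohort(sim_config(n_pairs = n_pairs, seed = 20000 + r))
        m <- adjust_batch(co$measurements)
        kept <- exclude_outliers(m, "by_age_band")$kept
        f <- fit_lgc(lgc_spec(), kept, co$individuals)
        ci <- confint(f)
        c(coef(f), converged = as.numeric(f$converged),
          setNames(as.numeric(ci[names(truth), 1] <= truth &
                                truth <= ci[names(truth), 2]),
                   paste0("cover_", names(truth))))
      }, numeric(9)))
    }
    memo[[key]]
  }
})

cross_sectional_replicates <- local({
  memo <- new.env()
  function(n_rep = 50, n_pairs = 318) {
    key <- paste0("r", n_rep, "_", n_pairs)
    if (is.null(memo[[key]])) {
      memo[[key]] <- t(vapply(seq_len(n_rep), function(r) {
        co <- simulate_cohort(cross_sectional_config(n_pairs = n_pairs,
                                                     seed = 30000 + r))
        m <- adjust_batch(co$measurements)
        cross <- exclude_outliers(first_measurements(m), "overall")$kept
        dat <- merge(cross, co$individuals[, c("individual_id", "sex")],
                     by = "individual_id")
        dat$female <- as.numeric(dat$sex == "female")
        f <- fit_cluster_ols(ts_adjusted ~ age_at_draw + female, dat,
                             dat$pair_id)
        ci <- f$ci_95
        c(age = unname(coef(f)["age_at_draw"]),
          female = unname(coef(f)["female"]),
          cover_age = as.numeric(ci["age_at_draw", 1] <= -0.0022 &
                                   -0.0022 <= ci["age_at_draw", 2]))
      }, numeric(3)))
    }
    memo[[key]]
  }
})
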