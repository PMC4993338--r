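#' Simulate a longitudinal twin cohort of telomere measurements
#'
#' Draws a cohort of same-sex twin pairs with repeated qPCR T/S-ratio
#' measurements under the piecewise latent growth curve generating model of
#' [sim_config()]. The expected trajectory for individual i of pair j at age
#' t is
#' \deqn{\mu = I + S_1 B_1(t) + S_2 B_2(t) + \beta_{sex} male_i +
#'   \beta_{grs} (GRS_i - \overline{GRS}) + (a_j + b_{ij})'(1, B_1, B_2) +
#'   \gamma_{plate} + \epsilon,}
#' where \eqn{B_1(t) = \min(t - c, 0)} and \eqn{B_2(t) = \max(t - c, 0)} are
#' the pre/post-knot age bases, \eqn{a_j} is shared by both twins of a pair
#' and \eqn{b_{ij}} is individual-specific. Attrition is monotone: once an
#' individual misses an occasion they contribute no later occasions. Twins
#' of a pair share their baseline age (and hence measurement ages), sex and
#' zygosity, but drop out independently.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; overrides `config$seed`. One of the two must be
#'   supplied. Identical configuration and seed give identical output.
#'
#' @return A list of class `twin_cohort` with components
#'   \describe{
#'     \item{individuals}{one row per person: `individual_id`, `pair_id`,
#'       `zygosity` ("MZ"/"DZ"), `sex` ("male"/"female"), `baseline_age`.}
#'     \item{measurements}{long format, one row per LTL sample:
#'       `individual_id`, `pair_id`, `occasion`, `age_at_draw`, `plate_id`,
#'       `ts_raw`, `ts_adjusted` (NA until [adjust_batch()]), `dup1`, `dup2`
#'       (NA until [simulate_duplicates()]).}
#'     \item{genotypes}{`individual_id` plus one risk-allele dosage column
#'       (0/1/2) per SNP of [default_risk_allele_map()].}
#'   }
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (is.null(seed)) stop("a seed is required (in the config or as `seed`)")
  set.seed(as.integer(seed))

  P <- config$n_pairs
  n_occ <- length(config$occasion_gaps) + 1L
  fe <- config$fixed_effects

  pair_id <- sprintf("P%04d", seq_len(P))
  pair_sex <- ifelse(runif(P) < config$prop_female_pairs, "female", "male")
  pair_zyg <- ifelse(runif(P) < config$prop_mz, "MZ", "DZ")
  # truncated-normal baseline age via inverse CDF
  lo <- pnorm((config$min_age - config$baseline_age_mean) / config$baseline_age_sd)
  pair_age0 <- config$baseline_age_mean +
    config$baseline_age_sd * qnorm(lo + runif(P) * (1 - lo))

  individuals <- data.frame(
    individual_id = paste0(rep(pair_id, each = 2), "_", rep(1:2, P)),
    pair_id = rep(pair_id, each = 2),
    zygosity = rep(pair_zyg, each = 2),
    sex = rep(pair_sex, each = 2),
    baseline_age = rep(pair_age0, each = 2),
    stringsAsFactors = FALSE
  )
  N <- nrow(individuals)

  # random growth deviations: a_j shared within pair, b_ij individual
  a_pair <- rmvn0(P, config$between_pair_cov)
  b_ind <- rmvn0(N, config$within_pair_cov)

  # genotypes: 7 independent binomial(2, freq) risk-allele dosages
  rsids <- default_risk_allele_map()$rsid
  geno <- vapply(config$allele_freqs,
                 function(f) rbinom(N, 2L, f), integer(N))
  colnames(geno) <- rsids
  genotypes <- data.frame(individual_id = individuals$individual_id, geno,
                          stringsAsFactors = FALSE, check.names = FALSE)
  grs <- rowSums(geno)
  grs_c <- grs - mean(grs)

  # monotone attrition
  present <- matrix(FALSE, N, n_occ)
  keep <- matrix(runif(N * n_occ) < rep(config$retention[seq_len(n_occ)],
                                        each = N), N, n_occ)
  present[, 1] <- keep[, 1]
  for (k in seq_len(n_occ)[-1]) present[, k] <- present[, k - 1] & keep[, k]

  occ_offsets <- c(0, cumsum(config$occasion_gaps))
  plate_eff <- rnorm(config$plate_count, 0, config$plate_effect_sd)
  male <- as.numeric(individuals$sex == "male")

  rows <- vector("list", n_occ)
  for (k in seq_len(n_occ)) {
    idx <- which(present[, k])
    if (!length(idx)) next
    age <- individuals$baseline_age[idx] + occ_offsets[k]
    basis <- cbind(1, age_basis(age, config$centering_age))
    mu <- fe$intercept + fe$slope1 * basis[, 2] + fe$slope2 * basis[, 3] +
      fe$sex_effect * male[idx] + fe$grs_effect * grs_c[idx] +
      rowSums(basis * a_pair[(idx + 1L) %/% 2L, , drop = FALSE]) +
      rowSums(basis * b_ind[idx, , drop = FALSE])
    plate <- ((seq_along(idx) - 1L) %% config$plate_count) + 1L
    ts_raw <- mu + plate_eff[plate] + rnorm(length(idx), 0, config$residual_sd)
    rows[[k]] <- data.frame(
      individual_id = individuals$individual_id[idx],
      pair_id = individuals$pair_id[idx],
      occasion = k, age_at_draw = age,
      plate_id = sprintf("plate%02d", plate),
      ts_raw = ts_raw, ts_adjusted = NA_real_,
      dup1 = NA_real_, dup2 = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  measurements <- do.call(rbind, rows)
  measurements <- measurements[order(measurements$individual_id,
                                     measurements$occasion), ]
  rownames(measurements) <- NULL

  out <- list(individuals = individuals, measurements = measurements,
              genotypes = genotypes)
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  class(out) <- "twin_cohort"
  out
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Twin cohort: %d individuals in %d pairs, %d LTL samples\n",
              nrow(x$individuals), length(unique(x$individuals$pair_id)),
              nrow(x$measurements)))
  tab <- table(x$measurements$occasion)
  cat("  samples per occasion:", paste(tab, collapse = ", "), "\n")
  invisible(x)
}

# n draws from N(0, Sigma) via the symmetric square root (works for PSD,
# including singular, Sigma)
rmvn0 <- function(n, sigma) {
  d <- nrow(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(rnorm(n * d), n, d) %*% rt
}

#' Simulate qPCR duplicate measurements
#'
#' Fills the `dup1`/`dup2` columns with two noisy replicates of each raw
#' T/S-ratio. Replicates are `ts_raw * (1 + s * z)` with independent
#' standard-normal `z` and `s = duplicate_cv * sqrt(pi / 2)`; the sqrt(pi/2)
#' factor compensates the downward bias of the two-replicate SD, so that
#' the expected duplicate-pair coefficient of variation reported by
#' [compute_cv()] equals `duplicate_cv`.
#'
#' @param measurements A measurement table with a `ts_raw` column.
#' @param duplicate_cv Target duplicate CV as a fraction (>= 0).
#' @return The measurement table with `dup1` and `dup2` filled.
#' @export
simulate_duplicates <- function(measurements, duplicate_cv) {
  stopifnot(duplicate_cv >= 0)
  n <- nrow(measurements)
  s <- duplicate_cv * sqrt(pi / 2)
  measurements$dup1 <- measurements$ts_raw * (1 + s * rnorm(n))
  measurements$dup2 <- measurements$ts_raw * (1 + s * rnorm(n))
  measurements
}

#' Write the three cohort tables as CSV files
#'
#' @param cohort A `twin_cohort` object (or any list with `individuals`,
#'   `measurements`, `genotypes` data frames).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("individuals.csv", "measurements.csv",
                            "genotypes.csv"))
  write.csv(cohort$individuals, paths[1], row.names = FALSE)
  write.csv(cohort$measurements, paths[2], row.names = FALSE)
  write.csv(cohort$genotypes, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read cohort tables written by [write_cohort_csv()]
#'
#' @param dir Directory containing `individuals.csv`, `measurements.csv`
#'   and `genotypes.csv`.
#' @return A `twin_cohort` list.
#' @export
read_cohort_csv <- function(dir) {
  out <- list(
    individuals = read.csv(file.path(dir, "individuals.csv"),
                           stringsAsFactors = FALSE),
    measurements = read.csv(file.path(dir, "measurements.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(ts_adjusted = "numeric",
                                           dup1 = "numeric",
                                           dup2 = "numeric")),
    genotypes = read.csv(file.path(dir, "genotypes.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  )
  class(out) <- "twin_cohort"
  out
}
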