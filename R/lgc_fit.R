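#' Assemble latent growth curve model data grouped by twin pair
#'
#' Merges the long-format measurement table with the individual table (and
#' an optional genetic risk score), builds the fixed-effect design and the
#' growth-basis matrices, and groups everything by twin pair for the
#' pairwise multivariate-normal likelihood. Sex is coded male = 1; the GRS
#' is centered on its mean over the analysed individuals. Rows with a
#' missing response or covariate are dropped with a message.
#'
#' When the spec has `slope1` but not `slope2`, the slope attaches to the
#' full centered age `(age - c)`, expressing a single linear rate; with
#' both slopes active, `slope1` and `slope2` use the pre- and post-knot
#' limbs `B1`, `B2` of [age_basis()].
#'
#' @param spec An [lgc_spec()].
#' @param measurements Measurement table (needs `individual_id`, `pair_id`,
#'   `age_at_draw` and the response column).
#' @param individuals Individual table (needs `individual_id`, `sex`).
#' @param grs Optional named vector of genetic risk scores (names =
#'   individual IDs), required when the spec uses `grs`.
#' @param response Response column, default `"ts_adjusted"`.
#' @return Object of class `lgc_data`.
#' @export
lgc_data <- function(spec, measurements, individuals, grs = NULL,
                     response = "ts_adjusted") {
  stopifnot(inherits(spec, "lgc_spec"))
  need <- c("individual_id", "pair_id", "age_at_draw", response)
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  df <- merge(measurements[, need],
              individuals[, c("individual_id", "sex")],
              by = "individual_id", sort = FALSE)
  df$male <- as.numeric(df$sex == "male")
  if ("grs" %in% c(spec$covariates, unlist(strsplit(spec$interactions, ":")))) {
    if (is.null(grs)) stop("spec uses grs but no scores were supplied")
    grs_c <- center_grs(grs[match(unique(df$individual_id), names(grs))])
    df$grs <- grs_c[match(df$individual_id, names(grs_c))]
  } else {
    df$grs <- 0
  }

  keep <- !is.na(df[[response]]) & !is.na(df$male) & !is.na(df$grs)
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing response or covariate")
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable rows")
  df <- df[order(df$pair_id, df$individual_id, df$age_at_draw), ]

  two_slope <- all(c("slope1", "slope2") %in% spec$growth)
  B <- age_basis(df$age_at_draw, spec$centering_age)
  basis_cols <- list(intercept = rep(1, nrow(df)),
                     slope1 = if (two_slope) B[, "b1"] else B[, "b1"] + B[, "b2"],
                     slope2 = B[, "b2"])
  Z <- do.call(cbind, basis_cols[spec$growth])
  colnames(Z) <- spec$growth

  cov_cols <- list(sex = df$male, grs = df$grs)
  int_cols <- lapply(spec$interactions, function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    get_col <- function(pp) {
      if (pp %in% colnames(Z)) Z[, pp] else cov_cols[[pp]]
    }
    get_col(parts[1]) * get_col(parts[2])
  })
  names(int_cols) <- spec$interactions
  X <- cbind(Z, do.call(cbind, c(cov_cols[spec$covariates], int_cols)))
  colnames(X) <- spec_fixed_terms(spec)
  y <- df[[response]]

  d <- ncol(Z)
  pairs <- lapply(split(seq_len(nrow(df)), df$pair_id), function(ii) {
    ids <- df$individual_id[ii]
    member <- match(ids, unique(ids))
    m <- max(member)
    zw <- matrix(0, length(ii), d * m)
    for (j in seq_len(m)) {
      rows_j <- member == j
      zw[rows_j, ((j - 1) * d + 1):(j * d)] <- Z[ii[rows_j], , drop = FALSE]
    }
    list(X = X[ii, , drop = FALSE], y = y[ii],
         zb = Z[ii, , drop = FALSE], zw = zw, m = as.integer(m))
  })

  out <- list(spec = spec, pairs = pairs, X = X, y = y, frame = df, d = d,
              n_pairs = length(pairs),
              n_individuals = length(unique(df$individual_id)),
              n_samples = nrow(df))
  class(out) <- "lgc_data"
  out
}

#' Evaluate the -2 log-likelihood of an LGC model
#'
#' The observations of a twin pair are jointly multivariate normal with
#' mean `X beta` and covariance
#' `Zb Sigma_B Zb' + blockdiag_twins(Zw Sigma_W Zw') + sigma^2 I`;
#' pairs are independent, so the total -2 log-likelihood is the sum of the
#' per-pair terms. Unbalanced and missing occasions are handled by row
#' deletion (each pair contributes only its observed rows).
#'
#' @param params List with `fixed` (named vector in the order of
#'   `spec_fixed_terms`), `between_pair_cov`, `within_pair_cov` (d x d),
#'   and `residual_var`.
#' @param data An [lgc_data()] object.
#' @return The -2 log-likelihood; `+Inf` (with a warning) if the supplied
#'   covariance parameters make any pair covariance non-positive-definite.
#' @export
neg2_loglik <- function(params, data) {
  stopifnot(inherits(data, "lgc_data"))
  d <- data$d
  sb <- as.matrix(params$between_pair_cov)
  sw <- as.matrix(params$within_pair_cov)
  if (!all(dim(sb) == d) || !all(dim(sw) == d)) {
    stop("covariance dimension must equal the number of growth terms (", d, ")")
  }
  if (params$residual_var < 0) {
    warning("negative residual variance; returning +Inf")
    return(Inf)
  }
  beta <- params$fixed[spec_fixed_terms(data$spec)]
  if (anyNA(beta)) stop("params$fixed must name every fixed-effect term")
  res <- lgc_deviance_cpp(data$pairs, sb, sw, params$residual_var,
                          as.numeric(beta), FALSE)
  if (!isTRUE(res$ok)) {
    warning("non-positive-definite covariance; returning +Inf")
    return(Inf)
  }
  res$deviance
}

# log-Cholesky packing: lower-triangular factor with log-diagonal
theta_to_cov <- function(theta, d) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

cov_to_theta <- function(sigma, d) {
  ev <- eigen(sigma, symmetric = TRUE)
  sigma <- ev$vectors %*% (pmax(ev$values, 1e-10) * t(ev$vectors))
  L <- t(chol(sigma))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

#' Fit a latent growth curve model by maximum likelihood
#'
#' Maximizes the likelihood of [neg2_loglik()] over unconstrained fixed
#' effects and log-Cholesky-parameterized random-effect covariances. The
#' fixed effects are profiled out by generalized least squares at each
#' variance-parameter evaluation, so the optimizer works on the
#' `d(d+1) + 1` variance parameters only. Estimation is plain ML (not
#' REML), so -2LL differences between fits with different fixed effects
#' are valid likelihood-ratio statistics. On non-convergence one
#' deterministic random restart from perturbed starting values is tried.
#'
#' @param spec An [lgc_spec()].
#' @param measurements,individuals,grs,response Passed to [lgc_data()];
#'   alternatively supply a prebuilt `lgc_data` via `data`.
#' @param data Optional [lgc_data()] (overrides the table arguments).
#' @param start Optional parameter list (as in [neg2_loglik()]) providing
#'   starting values for the covariance parameters.
#' @param bic_n Sample-size definition for BIC: `"pairs"` (default,
#'   mirroring the subject count of mixed-model software), `"individuals"`
#'   or `"observations"`.
#' @param control Control list passed to [stats::nlminb()].
#' @param restart_seed Seed for the perturbed restart.
#' @return Object of class `lgc_fit` with elements `params` (estimates),
#'   `minus2ll`, `aic`, `bic`, `parameter_count`, `fixed_vcov`,
#'   `converged`, and the sample sizes.
#' @export
fit_lgc <- function(spec, measurements = NULL, individuals = NULL,
                    grs = NULL, response = "ts_adjusted", data = NULL,
                    start = NULL, bic_n = c("pairs", "individuals",
                                            "observations"),
                    control = list(), restart_seed = 1L) {
  bic_n <- match.arg(bic_n)
  if (is.null(data)) {
    data <- lgc_data(spec, measurements, individuals, grs, response)
  } else {
    stopifnot(inherits(data, "lgc_data"))
    spec <- data$spec
  }
  if (data$n_pairs < 2) stop("need at least 2 pairs")
  d <- data$d
  nb <- d * (d + 1) / 2

  # moment-based starting values: OLS residual variance split
  # between-pair / within-pair / residual as 50/25/25, slope SDs at 1/20
  # of the intercept SD on each level
  if (is.null(start)) {
    ols <- lm.fit(data$X, data$y)
    s2 <- sum(ols$residuals^2) / max(1, length(data$y) - ncol(data$X))
    mk <- function(frac) {
      v <- rep(frac * s2 / 400, d)
      v[1] <- frac * s2
      diag(v, d)
    }
    theta0 <- c(cov_to_theta(mk(0.5), d), cov_to_theta(mk(0.25), d),
                0.5 * log(0.25 * s2))
  } else {
    theta0 <- c(cov_to_theta(as.matrix(start$between_pair_cov), d),
                cov_to_theta(as.matrix(start$within_pair_cov), d),
                0.5 * log(start$residual_var))
  }

  objective <- function(theta) {
    res <- lgc_deviance_cpp(data$pairs, theta_to_cov(theta[1:nb], d),
                            theta_to_cov(theta[nb + 1:nb], d),
                            exp(2 * theta[2 * nb + 1]), NULL, TRUE)
    if (!isTRUE(res$ok)) return(1e10)
    res$deviance
  }

  ctrl <- modifyList(list(iter.max = 500, eval.max = 3000, rel.tol = 1e-10),
                     control)
  opt <- nlminb(theta0, objective, control = ctrl)
  converged <- opt$convergence == 0
  if (!converged) {
    # polish from the current solution; clears many spurious
    # singular/false-convergence reports at variance boundaries
    opt_p <- nlminb(opt$par, objective, control = ctrl)
    if (opt_p$objective <= opt$objective + 1e-8) {
      opt <- opt_p
      converged <- opt_p$convergence == 0
    }
  }
  if (!converged) {
    opt2 <- with_preserved_seed(restart_seed, {
      nlminb(theta0 + rnorm(length(theta0), 0, 0.3), objective,
             control = ctrl)
    })
    if (opt2$objective <= opt$objective) {
      opt <- opt2
      converged <- opt2$convergence == 0
    }
  }

  theta <- opt$par
  final <- lgc_deviance_cpp(data$pairs, theta_to_cov(theta[1:nb], d),
                            theta_to_cov(theta[nb + 1:nb], d),
                            exp(2 * theta[2 * nb + 1]), NULL, TRUE)
  if (!isTRUE(final$ok)) stop("likelihood not evaluable at the optimum")
  beta <- setNames(as.numeric(final$beta), colnames(data$X))
  params <- list(fixed = beta,
                 between_pair_cov = theta_to_cov(theta[1:nb], d),
                 within_pair_cov = theta_to_cov(theta[nb + 1:nb], d),
                 residual_var = exp(2 * theta[2 * nb + 1]))
  dimnames(params$between_pair_cov) <- list(spec$growth, spec$growth)
  dimnames(params$within_pair_cov) <- list(spec$growth, spec$growth)

  k <- count_parameters(spec)
  m2ll <- opt$objective
  n_bic <- switch(bic_n, pairs = data$n_pairs,
                  individuals = data$n_individuals,
                  observations = data$n_samples)
  fixed_vcov <- solve(final$info)
  dimnames(fixed_vcov) <- list(colnames(data$X), colnames(data$X))

  out <- list(spec = spec, params = params, minus2ll = m2ll,
              aic = m2ll + 2 * k, bic = m2ll + log(n_bic) * k,
              parameter_count = k, fixed_vcov = fixed_vcov,
              converged = converged, n_pairs = data$n_pairs,
              n_individuals = data$n_individuals,
              n_samples = data$n_samples, bic_n = bic_n,
              optim = list(iterations = opt$iterations,
                           message = opt$message,
                           convergence = opt$convergence))
  class(out) <- "lgc_fit"
  out
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
coef.lgc_fit <- function(object, ...) object$params$fixed

#' @export
vcov.lgc_fit <- function(object, ...) object$fixed_vcov

#' @export
logLik.lgc_fit <- function(object, ...) {
  structure(-object$minus2ll / 2, df = object$parameter_count,
            nobs = object$n_samples, class = "logLik")
}

#' @export
confint.lgc_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$params$fixed
  se <- sqrt(diag(object$fixed_vcov))
  q <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - q * se, est + q * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.lgc_fit <- function(x, digits = 4, ...) {
  cat(sprintf("LGC fit (%s): -2LL = %.1f, %d parameters, AIC = %.1f, BIC = %.1f\n",
              paste(x$spec$growth, collapse = "+"), x$minus2ll,
              x$parameter_count, x$aic, x$bic))
  cat(sprintf("  %d samples, %d individuals, %d pairs; converged: %s\n",
              x$n_samples, x$n_individuals, x$n_pairs, x$converged))
  est <- x$params$fixed
  se <- sqrt(diag(x$fixed_vcov))
  tab <- data.frame(estimate = est, se = se,
                    ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se)
  print(round(tab, digits))
  cat("Random effects (SDs): between-pair",
      paste(signif(sqrt(diag(x$params$between_pair_cov)), 3), collapse = ", "),
      "| within-pair",
      paste(signif(sqrt(diag(x$params$within_pair_cov)), 3), collapse = ", "),
      "| residual", signif(sqrt(x$params$residual_var), 3), "\n")
  invisible(x)
}

#' Chi-square difference test from -2 log-likelihood values
#'
#' The likelihood-ratio comparison in its raw arithmetic form: the change
#' in -2LL between a reduced and a full nested model referred to a
#' chi-square distribution with df equal to the parameter-count
#' difference.
#'
#' @param m2ll_reduced,m2ll_full -2 log-likelihoods of the two models.
#' @param parms_reduced,parms_full Their parameter counts.
#' @return List with `delta_minus2ll`, `df`, `p`.
#' @export
chisq_diff_test <- function(m2ll_reduced, m2ll_full, parms_reduced,
                            parms_full) {
  df <- parms_full - parms_reduced
  if (df < 0) stop("full model cannot have fewer parameters than reduced")
  delta <- m2ll_reduced - m2ll_full
  p <- if (df == 0) {
    # chi-square with 0 df is a point mass at 0
    as.numeric(delta <= 1e-8)
  } else {
    pchisq(max(delta, 0), df, lower.tail = FALSE)
  }
  list(delta_minus2ll = delta, df = df, p = p)
}

#' Likelihood-ratio test between two nested LGC fits
#'
#' @param fit_reduced,fit_full Converged [fit_lgc()] results; the reduced
#'   spec must be nested in the full spec.
#' @param tol Tolerance for a negative -2LL difference before declaring an
#'   optimizer failure.
#' @return List with `delta_minus2ll`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_full, tol = 1e-3) {
  stopifnot(inherits(fit_reduced, "lgc_fit"), inherits(fit_full, "lgc_fit"))
  if (!spec_is_nested(fit_reduced$spec, fit_full$spec)) {
    stop("fit_reduced is not nested in fit_full")
  }
  if (!fit_reduced$converged || !fit_full$converged) {
    stop("both fits must have converged")
  }
  delta <- fit_reduced$minus2ll - fit_full$minus2ll
  if (delta < -tol) {
    stop("full model has higher -2LL than reduced (", signif(delta, 3),
         "): optimizer failure")
  }
  chisq_diff_test(fit_reduced$minus2ll, fit_full$minus2ll,
                  fit_reduced$parameter_count, fit_full$parameter_count)
}

#' Model-comparison table for a ladder of nested LGC fits
#'
#' @param fits Named list of `lgc_fit` objects, ordered so that each model
#'   is nested in the next.
#' @param reference Integer vector: for each model after the first, the
#'   index of its reference model (default the previous one).
#' @return Data frame with -2LL, parameter count, AIC, BIC, the -2LL
#'   change against the reference, df and p.
#' @export
compare_models <- function(fits, reference = NULL) {
  k <- length(fits)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_len(k))
  if (is.null(reference)) reference <- c(NA, seq_len(k - 1))
  out <- data.frame(model = names(fits),
                    minus2ll = vapply(fits, `[[`, 0, "minus2ll"),
                    parms = vapply(fits, `[[`, 0L, "parameter_count"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    reference = NA_character_, delta_m2ll = NA_real_,
                    df = NA_integer_, p = NA_real_, row.names = NULL)
  for (i in seq_len(k)) {
    if (is.na(reference[i])) next
    lrt <- likelihood_ratio_test(fits[[reference[i]]], fits[[i]])
    out$reference[i] <- names(fits)[reference[i]]
    out$delta_m2ll[i] <- lrt$delta_minus2ll
    out$df[i] <- lrt$df
    out$p[i] <- lrt$p
  }
  out
}

#' Predicted population trajectory from an LGC fit
#'
#' Fixed-effects-only prediction over an age grid: piecewise linear with
#' the knot at the centering age. At the centering age, for the reference
#' sex (female) and a mean GRS, the prediction equals the fitted
#' intercept; without sex interactions the male and female curves are
#' parallel and differ by the sex coefficient at every age.
#'
#' @param fit A converged `lgc_fit`.
#' @param ages Age grid in years.
#' @param sex `"female"` or `"male"`.
#' @param grs Centered GRS value (0 = cohort mean).
#' @return Data frame with `age`, `sex`, `grs`, `ts_predicted`.
#' @export
predict_trajectory <- function(fit, ages, sex = c("female", "male"),
                               grs = 0) {
  sex <- match.arg(sex)
  spec <- fit$spec
  male <- as.numeric(sex == "male")
  two_slope <- all(c("slope1", "slope2") %in% spec$growth)
  B <- age_basis(ages, spec$centering_age)
  basis_cols <- list(intercept = rep(1, length(ages)),
                     slope1 = if (two_slope) B[, "b1"] else B[, "b1"] + B[, "b2"],
                     slope2 = B[, "b2"])
  cov_cols <- list(sex = rep(male, length(ages)),
                   grs = rep(grs, length(ages)))
  cols <- c(basis_cols[spec$growth], cov_cols[spec$covariates])
  for (term in spec$interactions) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    pick <- function(pp) if (pp %in% names(basis_cols) && pp %in% spec$growth)
      basis_cols[[pp]] else cov_cols[[pp]]
    cols[[term]] <- pick(parts[1]) * pick(parts[2])
  }
  X <- do.call(cbind, cols[spec_fixed_terms(spec)])
  data.frame(age = ages, sex = sex, grs = grs,
             ts_predicted = as.numeric(X %*% fit$params$fixed))
}
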