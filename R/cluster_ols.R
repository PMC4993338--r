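#' Linear regression with cluster-robust (sandwich) standard errors
#'
#' Ordinary least squares point estimates with a sandwich covariance
#' estimator that is robust to arbitrary correlation within clusters —
#' here, within twin pairs:
#' \deqn{V = c \, (X'X)^{-1} \Big[\sum_g X_g' e_g e_g' X_g\Big] (X'X)^{-1},}
#' where the sum runs over clusters and `e_g` are the OLS residuals of
#' cluster g. The small-sample factor `c` is the CR1-style
#' `G/(G-1) * (N-1)/(N-p)` by default (`ssc = "CR1"`); `ssc = "CR0"` uses
#' `c = 1`. Inference uses a t reference distribution with G - 1 degrees
#' of freedom. With every cluster of size one the estimator reduces to the
#' heteroskedasticity-robust sandwich (up to the chosen factor).
#'
#' @param formula Model formula, e.g. `ts_adjusted ~ age_at_draw + sex`.
#' @param data Data frame.
#' @param cluster Cluster identifiers: a vector of length `nrow(data)` or
#'   the name of a column of `data` (e.g. `"pair_id"`).
#' @param ssc Small-sample correction, `"CR1"` (default) or `"CR0"`.
#' @param conf_level Confidence level for the reported intervals.
#' @return Object of class `cluster_ols`: list with `coefficients`,
#'   `robust_vcov`, `se`, `statistic`, `p_values`, `ci_95` (matrix), `df`,
#'   `n_obs`, `n_clusters`, `ols_fit`.
#' @export
fit_cluster_ols <- function(formula, data, cluster, ssc = c("CR1", "CR0"),
                            conf_level = 0.95) {
  ssc <- match.arg(ssc)
  if (is.character(cluster) && length(cluster) == 1) {
    if (!cluster %in% names(data)) stop("no column named '", cluster, "'")
    cluster <- data[[cluster]]
  }
  mf <- model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- complete.cases(mf) & !is.na(cluster)
  mf <- mf[keep, , drop = FALSE]
  cluster <- factor(cluster[keep])
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is singular; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  G <- nlevels(cluster)
  if (G < 2) stop("need at least 2 clusters")
  n <- nrow(X); p <- ncol(X)

  beta <- qr.coef(qrX, y)
  e <- as.numeric(y - X %*% beta)
  bread <- solve(crossprod(X))
  Sg <- rowsum(X * e, cluster)  # G x p matrix of cluster score sums
  meat <- crossprod(Sg)
  cfac <- if (ssc == "CR1") G / (G - 1) * (n - 1) / (n - p) else 1
  V <- cfac * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))

  se <- sqrt(diag(V))
  df <- G - 1
  tstat <- beta / se
  pvals <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  q <- qt(1 - (1 - conf_level) / 2, df)
  ci <- cbind(lower = beta - q * se, upper = beta + q * se)

  out <- list(coefficients = beta, robust_vcov = V, se = se,
              statistic = tstat, p_values = pvals, ci_95 = ci, df = df,
              n_obs = n, n_clusters = G, conf_level = conf_level,
              ssc = ssc, formula = formula)
  class(out) <- "cluster_ols"
  out
}

#' @export
coef.cluster_ols <- function(object, ...) object$coefficients

#' @export
vcov.cluster_ols <- function(object, ...) object$robust_vcov

#' @export
confint.cluster_ols <- function(object, ...) object$ci_95

#' @export
print.cluster_ols <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Cluster-robust OLS (%s, t with %d df): %d obs in %d clusters\n",
    x$ssc, x$df, x$n_obs, x$n_clusters))
  tab <- coef_table(x)
  print(format(tab, digits = digits))
  invisible(x)
}

#' Coefficient table of a cluster-robust fit
#'
#' @param fit A `cluster_ols` object.
#' @return Data frame with estimate, robust SE, CI bounds, t and p.
#' @export
coef_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             robust_se = unname(fit$se),
             ci_lower = unname(fit$ci_95[, "lower"]),
             ci_upper = unname(fit$ci_95[, "upper"]),
             t = unname(fit$statistic),
             p = unname(fit$p_values),
             row.names = NULL)
}
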