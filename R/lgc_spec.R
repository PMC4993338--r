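#' Piecewise age basis around a knot
#'
#' Splits centered age into a pre-knot and a post-knot limb:
#' `B1 = min(age - c, 0)`, `B2 = max(age - c, 0)`, so `B1 + B2 = age - c`
#' and both are zero at the knot.
#'
#' @param age Ages in years.
#' @param centering_age Knot age `c` in years (default 69.3).
#' @return Two-column matrix `b1`, `b2`.
#' @export
age_basis <- function(age, centering_age = 69.3) {
  cbind(b1 = pmin(age - centering_age, 0),
        b2 = pmax(age - centering_age, 0))
}

#' Specify a latent growth curve model
#'
#' Defines the fixed- and random-effect structure of the LTL growth model:
#' which growth terms are active (intercept; linear slope before the knot;
#' linear slope after the knot), which covariates enter the fixed effects,
#' and which interactions. Both random-effect levels (between twin pairs
#' and within pairs, i.e. per individual) carry an unstructured covariance
#' over the active growth terms; the residual variance is a single value
#' shared across measurement occasions.
#'
#' The three standard models of the ladder are
#' `growth = "intercept"` (no change), `growth = c("intercept", "slope1")`
#' with `single_slope = TRUE` meaning slope1 spans the whole age range, and
#' the two-slope model `growth = c("intercept", "slope1", "slope2")`.
#' For the one-slope model supply `growth = c("intercept", "slope1")`: the
#' slope is then attached to the full centered age `(B1 + B2)` rather than
#' the pre-knot limb only, so it expresses a single linear rate of change.
#'
#' @param growth Subset of `c("intercept", "slope1", "slope2")`; must
#'   include `"intercept"`.
#' @param covariates Subset of `c("sex", "grs")`. Sex is coded male = 1
#'   here, so a negative coefficient means men have lower T/S-ratio; GRS is
#'   always centered before entry.
#' @param interactions Subset of `c("slope2:sex", "slope2:grs", "sex:grs")`;
#'   constituent terms must be present.
#' @param centering_age Knot and centering age in years.
#' @return Object of class `lgc_spec`.
#' @export
lgc_spec <- function(growth = c("intercept", "slope1", "slope2"),
                     covariates = "sex",
                     interactions = character(),
                     centering_age = 69.3) {
  growth <- match.arg(growth, c("intercept", "slope1", "slope2"),
                      several.ok = TRUE)
  if (!"intercept" %in% growth) stop("growth must include \"intercept\"")
  covariates <- if (length(covariates)) {
    match.arg(covariates, c("sex", "grs"), several.ok = TRUE)
  } else character()
  ok_int <- c("slope2:sex", "slope2:grs", "sex:grs")
  if (length(interactions) && !all(interactions %in% ok_int)) {
    stop("interactions must be among: ", paste(ok_int, collapse = ", "))
  }
  for (term in interactions) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    for (pp in parts) {
      if (!pp %in% c(growth, covariates)) {
        stop("interaction ", term, " needs term '", pp, "' in the model")
      }
    }
  }
  out <- list(growth = growth, covariates = covariates,
              interactions = interactions, centering_age = centering_age)
  class(out) <- "lgc_spec"
  out
}

#' @export
print.lgc_spec <- function(x, ...) {
  cat("LGC model spec (knot/centering at", x$centering_age, "years)\n")
  cat("  growth terms:", paste(x$growth, collapse = " + "), "\n")
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = " + "), "\n")
  if (length(x$interactions))
    cat("  interactions:", paste(x$interactions, collapse = " + "), "\n")
  cat("  parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Number of free parameters of an LGC specification
#'
#' Fixed effects (growth means, covariates, interactions) plus the unique
#' entries of the between-pair and within-pair random-effect covariances
#' (`d(d+1)/2` each, `d` = number of active growth terms) plus one shared
#' residual variance. The standard ladder with sex gives 5 (intercept
#' only), 10 (one slope) and 17 (two slopes); adding centered GRS gives 18
#' and a GRS-by-slope2 interaction 19.
#'
#' @param spec An `lgc_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "lgc_spec"))
  d <- length(spec$growth)
  n_fixed <- d + length(spec$covariates) + length(spec$interactions)
  as.integer(n_fixed + 2 * d * (d + 1) / 2 + 1)
}

# is `a` nested in `b`?
spec_is_nested <- function(a, b) {
  isTRUE(all.equal(a$centering_age, b$centering_age)) &&
    all(a$growth %in% b$growth) &&
    all(a$covariates %in% b$covariates) &&
    all(a$interactions %in% b$interactions)
}

# fixed-effect design column labels for a spec
spec_fixed_terms <- function(spec) {
  c(spec$growth, spec$covariates, spec$interactions)
}
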