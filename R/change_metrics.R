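#' All pairwise within-individual LTL changes
#'
#' For every individual, emits one record per ordered pair of measurement
#' occasions (all combinations, not just consecutive ones): an individual
#' with m samples contributes m(m-1)/2 records. Individuals with a single
#' sample contribute nothing.
#'
#' @param measurements Measurement table with `ts_adjusted` filled.
#' @param value Column holding the LTL value (default `"ts_adjusted"`).
#' @return Data frame with `individual_id`, `earlier_age`, `later_age`,
#'   `gap` (years, > 0), `delta` (later minus earlier T/S-ratio).
#' @export
pairwise_deltas <- function(measurements, value = "ts_adjusted") {
  if (any(is.na(measurements[[value]]))) {
    stop(value, " must be filled")
  }
  ord <- order(measurements$individual_id, measurements$age_at_draw)
  m <- measurements[ord, , drop = FALSE]
  by_id <- split(seq_len(nrow(m)), m$individual_id)
  recs <- lapply(by_id, function(ii) {
    k <- length(ii)
    if (k < 2) return(NULL)
    cmb <- utils::combn(k, 2)
    data.frame(individual_id = m$individual_id[ii[1]],
               earlier_age = m$age_at_draw[ii[cmb[1, ]]],
               later_age = m$age_at_draw[ii[cmb[2, ]]],
               gap = m$age_at_draw[ii[cmb[2, ]]] - m$age_at_draw[ii[cmb[1, ]]],
               delta = m[[value]][ii[cmb[2, ]]] - m[[value]][ii[cmb[1, ]]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(individual_id = character(0), earlier_age = numeric(0),
                      later_age = numeric(0), gap = numeric(0),
                      delta = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Fraction of within-individual comparisons showing elongation
#'
#' Percentage of pairwise deltas that are strictly positive (a tie counts
#' as non-elongation). Optionally stratified by the gap between
#' measurements rounded to whole years.
#'
#' @param deltas Output of [pairwise_deltas()].
#' @param stratify_by_gap If TRUE, also return the per-gap breakdown.
#' @return If `stratify_by_gap = FALSE`, a single percentage. Otherwise a
#'   list with `overall` and a `by_gap` data frame (`gap_years`, `n`,
#'   `pct_elongation`).
#' @export
elongation_fraction <- function(deltas, stratify_by_gap = FALSE) {
  if (nrow(deltas) == 0) stop("no delta records")
  overall <- 100 * mean(deltas$delta > 0)
  if (!stratify_by_gap) return(overall)
  gap_yr <- round(deltas$gap)
  tab <- aggregate(deltas$delta > 0, by = list(gap_years = gap_yr),
                   FUN = function(z) c(n = length(z), pct = 100 * mean(z)))
  by_gap <- data.frame(gap_years = tab$gap_years,
                       n = tab$x[, "n"],
                       pct_elongation = tab$x[, "pct"])
  list(overall = overall, by_gap = by_gap)
}

#' Tricube locally weighted linear trend
#'
#' Local linear regression at each query point using the span-nearest
#' neighbours with tricube weights: for query point x0 the bandwidth is
#' the distance to the q-th nearest data point (q = floor(span * n)) and
#' weights are `(1 - (d/h)^3)^3` for d < h. Matches the classical loess
#' smoother of degree 1.
#'
#' @param x,y Data points (at least 3).
#' @param xout Query points (default `x`).
#' @param span Fraction of points in each local neighbourhood, in (0, 1].
#' @return Fitted values at `xout`.
#' @export
loess_smooth <- function(x, y, xout = x, span = 0.75) {
  stopifnot(length(x) == length(y), span > 0, span <= 1)
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  q <- floor(span * n)
  if (q < 2) stop("span selects fewer than 2 points")
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h <= 0) {
      # all neighbours at x0 itself: local mean
      return(mean(y[d == 0]))
    }
    w <- numeric(n)
    inside <- d < h
    w[inside] <- (1 - (d[inside] / h)^3)^3
    if (sum(w > 0) < 2) stop("span selects fewer than 2 points at x = ", x0)
    xc <- x - x0
    sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
    swy <- sum(w * y); swxy <- sum(w * xc * y)
    det <- sw * swx2 - swx^2
    if (det <= .Machine$double.eps * sw * swx2) {
      return(swy / sw)  # degenerate neighbourhood: weighted mean
    }
    # intercept of the local line at x0
    (swx2 * swy - swx * swxy) / det
  }, numeric(1))
}
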