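#' Adjust raw T/S-ratios for qPCR plate batch effects
#'
#' Regresses `ts_raw` on plate-indicator fixed effects and re-scales the
#' residuals back to the T/S scale by adding the grand mean, so that after
#' adjustment every plate's mean equals the overall mean exactly. The
#' adjustment is fitted on all supplied records (before any outlier
#' exclusion) and is idempotent.
#'
#' @param measurements Measurement table with `ts_raw` and `plate_id`.
#' @return The table with `ts_adjusted` filled; records with missing
#'   `ts_raw` are left NA with a warning.
#' @export
adjust_batch <- function(measurements) {
  if (!all(c("ts_raw", "plate_id") %in% names(measurements))) {
    stop("measurements must have ts_raw and plate_id columns")
  }
  ok <- !is.na(measurements$ts_raw)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with missing ts_raw skipped")
  }
  if (any(is.na(measurements$plate_id[ok]))) {
    stop("every measurement needs a plate_id")
  }
  x <- measurements$ts_raw[ok]
  plate <- factor(measurements$plate_id[ok])
  plate_mean <- tapply(x, plate, mean)
  measurements$ts_adjusted <- NA_real_
  measurements$ts_adjusted[ok] <- x - plate_mean[plate] + mean(x)
  measurements
}

#' Decade age bands used for within-band outlier screening
#'
#' Closed-open bands `[50, 60)`, `[60, 70)`, `[70, 80)`, `[80, Inf)`.
#'
#' @return Data frame with `lower` and `upper` columns.
#' @export
default_age_bands <- function() {
  data.frame(lower = c(50, 60, 70, 80), upper = c(60, 70, 80, Inf))
}

#' Exclude extreme T/S-ratios by a k-SD rule
#'
#' Flags records whose adjusted T/S-ratio lies more than `k_sd` standard
#' deviations from the mean, either over the full set (`mode = "overall"`,
#' as used cross-sectionally) or within decade age bands
#' (`mode = "by_age_band"`, as used longitudinally). The rule is single
#' pass: mean and SD come from the pre-exclusion data and are not
#' recomputed after removals.
#'
#' @param measurements Measurement table with `ts_adjusted` filled (and
#'   `age_at_draw` when banding).
#' @param mode `"overall"` or `"by_age_band"`.
#' @param k_sd Positive multiplier; default 4.
#' @param bands Age-band table as from [default_age_bands()].
#' @return List with `kept` and `excluded` measurement tables; `excluded`
#'   gains a `reason` column recording the band and z-threshold applied.
#' @export
exclude_outliers <- function(measurements,
                             mode = c("overall", "by_age_band"),
                             k_sd = 4, bands = default_age_bands()) {
  mode <- match.arg(mode)
  stopifnot(k_sd > 0)
  if (nrow(measurements) == 0) {
    return(list(kept = measurements,
                excluded = cbind(measurements, reason = character(0))))
  }
  if (any(is.na(measurements$ts_adjusted))) {
    stop("ts_adjusted must be filled (run adjust_batch first)")
  }
  x <- measurements$ts_adjusted
  drop <- logical(length(x))
  reason <- character(length(x))
  if (mode == "overall") {
    if (length(x) >= 2) {
      m <- mean(x); s <- sd(x)
      drop <- abs(x - m) > k_sd * s
      reason[drop] <- sprintf("overall |z| > %g", k_sd)
    }
  } else {
    band <- findInterval(measurements$age_at_draw, c(bands$lower, Inf))
    band[measurements$age_at_draw < bands$lower[1]] <- 0L
    for (b in seq_len(nrow(bands))) {
      in_b <- which(band == b)
      if (length(in_b) < 2) {
        if (length(in_b) == 1) {
          message("age band [", bands$lower[b], ", ", bands$upper[b],
                  ") has < 2 records; no exclusion applied")
        }
        next
      }
      m <- mean(x[in_b]); s <- sd(x[in_b])
      bad <- in_b[abs(x[in_b] - m) > k_sd * s]
      drop[bad] <- TRUE
      reason[bad] <- sprintf("band [%g,%g) |z| > %g", bands$lower[b],
                             bands$upper[b], k_sd)
    }
  }
  excluded <- measurements[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[drop]
  else excluded$reason <- character(0)
  list(kept = measurements[!drop, , drop = FALSE], excluded = excluded)
}

#' Duplicate-based coefficient of variation of the assay
#'
#' Mean over samples of (SD of the duplicate pair / mean of the duplicate
#' pair), in percent. Scale invariant.
#'
#' @param measurements Table with `dup1` and `dup2` filled for at least one
#'   record.
#' @return CV in percent.
#' @export
compute_cv <- function(measurements) {
  ok <- !is.na(measurements$dup1) & !is.na(measurements$dup2)
  if (!any(ok)) stop("no records with both duplicate values present")
  d1 <- measurements$dup1[ok]; d2 <- measurements$dup2[ok]
  pair_sd <- abs(d1 - d2) / sqrt(2)
  pair_mean <- (d1 + d2) / 2
  100 * mean(pair_sd / pair_mean)
}

#' First available measurement per individual
#'
#' Selector for the cross-sectional dataset: each individual's earliest
#' available occasion.
#'
#' @param measurements Long-format measurement table.
#' @return One row per individual.
#' @export
first_measurements <- function(measurements) {
  ord <- order(measurements$individual_id, measurements$occasion)
  m <- measurements[ord, , drop = FALSE]
  out <- m[!duplicated(m$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
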