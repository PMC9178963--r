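#' Smooth an MO2 series into a continuous curve
#'
#' Fits a smoothing spline to the per-cycle MO2 values against time, the
#' smoothing parameter chosen by generalized cross-validation unless
#' overridden. The returned curve is evaluated on demand in minutes from
#' trial start.
#'
#' @param series an `mo2_series` with at least 8 entries.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by GCV.
#' @param df optional equivalent degrees of freedom (alternative override).
#' @return An object of class `mo2_curve`: a list with `fun` (a function of
#'   minutes), `spar` (the smoothing parameter used), `df`, and `range_min`
#'   (the time span covered).
#' @export
smooth_series <- function(series, spar = NULL, df = NULL) {
  if (nrow(series) < 8L) {
    stop("smoothing needs at least 8 MO2 values", call. = FALSE)
  }
  x <- series$mid_time_s / 60
  y <- series$mo2
  fit <- if (!is.null(spar)) {
    stats::smooth.spline(x, y, spar = spar)
  } else if (!is.null(df)) {
    stats::smooth.spline(x, y, df = df)
  } else {
    stats::smooth.spline(x, y, cv = FALSE)  # GCV
  }
  f <- function(t_min) stats::predict(fit, t_min)$y
  structure(list(fun = f, spar = fit$spar, df = fit$df,
                 range_min = range(x)),
            class = "mo2_curve")
}

# Accept an mo2_curve or a plain function of minutes.
curve_fun <- function(curve) {
  if (inherits(curve, "mo2_curve")) curve$fun
  else if (is.function(curve)) curve
  else stop("curve must be an mo2_curve or a function of minutes",
            call. = FALSE)
}

#' Time for a recovery curve to fall to a threshold
#'
#' Finds the first downward crossing of `threshold` after `t0_min`,
#' evaluating the curve on a 1-second grid and refining the crossing by
#' bisection between the bracketing grid points. If the curve already
#' starts at or below the threshold the time is 0; if it never crosses, the
#' `crossed` flag is `FALSE`. Later re-crossings are ignored.
#'
#' @param curve an `mo2_curve` from [smooth_series()], or any function of
#'   minutes.
#' @param t0_min recovery clock origin (time of MMR), minutes.
#' @param threshold MO2 threshold (> 0), same units as the series.
#' @param t_end_min end of the search window in minutes; defaults to the
#'   curve's fitted range.
#' @return A list with `time_min` (minutes from `t0_min`, or `NA`) and
#'   `crossed` (logical).
#' @export
time_to_threshold <- function(curve, t0_min, threshold, t_end_min = NULL) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  f <- curve_fun(curve)
  if (is.null(t_end_min)) {
    if (!inherits(curve, "mo2_curve")) {
      stop("t_end_min is required for a plain function curve", call. = FALSE)
    }
    t_end_min <- curve$range_min[2]
  }
  if (t_end_min <= t0_min) stop("search window is empty", call. = FALSE)
  grid <- seq(t0_min, t_end_min, by = 1 / 60)
  vals <- f(grid)
  if (vals[1] <= threshold) return(list(time_min = 0, crossed = TRUE))
  below <- which(vals < threshold)
  if (length(below) == 0L) return(list(time_min = NA_real_, crossed = FALSE))
  i <- below[1]
  root <- stats::uniroot(function(t) f(t) - threshold,
                         lower = grid[i - 1], upper = grid[i],
                         tol = 1e-8)$root
  list(time_min = root - t0_min, crossed = TRUE)
}

#' Recovery kinetics after an exhaustive chase
#'
#' Computes the two recovery durations used to characterise post-exercise
#' recovery: the time for the smoothed MO2 curve to fall to 50% of MMR
#' (short-term recovery) and the time to the end of EPOC, defined as the
#' first crossing of 20% above SMR. Both clocks start at the MMR
#' measurement.
#'
#' @param series an `mo2_series`.
#' @param smr,mmr trait values from [estimate_smr()] / [estimate_mmr()].
#' @param mmr_time_s timestamp of the MMR cycle, seconds.
#' @param spar optional smoothing parameter override.
#' @param epoc_factor EPOC-end threshold as a multiple of SMR
#'   (default 1.2, i.e. 20% above SMR).
#' @return An object of class `recovery_result`: a one-row data frame with
#'   `fish_id`, `time_mmr50_min`, `time_epoc_h`, `crossed_50`,
#'   `crossed_epoc`, `thresholds_overlap`, `smoothing_param`.
#' @export
recovery_metrics <- function(series, smr, mmr, mmr_time_s, spar = NULL,
                             epoc_factor = 1.2) {
  curve <- smooth_series(series, spar = spar)
  t0 <- mmr_time_s / 60
  thr50 <- 0.5 * mmr
  thr_epoc <- epoc_factor * smr
  r50 <- time_to_threshold(curve, t0, thr50)
  repoc <- time_to_threshold(curve, t0, thr_epoc)
  out <- data.frame(fish_id = attr(series, "fish_id"),
                    time_mmr50_min = r50$time_min,
                    time_epoc_h = repoc$time_min / 60,
                    crossed_50 = r50$crossed,
                    crossed_epoc = repoc$crossed,
                    thresholds_overlap = thr50 <= thr_epoc,
                    smoothing_param = curve$spar,
                    stringsAsFactors = FALSE)
  class(out) <- c("recovery_result", "data.frame")
  out
}
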