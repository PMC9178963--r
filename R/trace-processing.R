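#' Oxygen trace container
#'
#' Wraps a timestamped dissolved-oxygen record from one respirometry chamber
#' as a data frame with columns `time_s`, `o2_mg_per_l`, `temp_c` and
#' optionally `phase` (`"measure"`/`"flush"`), carrying the chamber volume
#' and fish identity as attributes. Time must be strictly increasing and
#' oxygen non-negative.
#'
#' @param samples data frame with numeric columns `time_s`, `o2_mg_per_l`,
#'   `temp_c`, and optionally a character `phase` column.
#' @param chamber_volume_l chamber volume in litres (> 0).
#' @param fish_id fish identifier, or `NA` for an empty-chamber
#'   (background) trial.
#' @return An object of class `o2_trace` (a data frame).
#' @export
o2_trace <- function(samples, chamber_volume_l = 2, fish_id = NA_character_) {
  req <- c("time_s", "o2_mg_per_l", "temp_c")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop("`samples` must be a data frame with columns time_s, o2_mg_per_l, temp_c",
         call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("empty trace", call. = FALSE)
  if (any(diff(samples$time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(samples$o2_mg_per_l < 0)) {
    stop("dissolved oxygen must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(samples$temp_c))) {
    stop("temperature must be finite", call. = FALSE)
  }
  stopifnot_scalar(chamber_volume_l, "chamber_volume_l")
  if (chamber_volume_l <= 0) stop("chamber_volume_l must be > 0", call. = FALSE)
  out <- as.data.frame(samples)
  attr(out, "chamber_volume_l") <- chamber_volume_l
  attr(out, "fish_id") <- fish_id
  class(out) <- c("o2_trace", "data.frame")
  out
}

#' @export
print.o2_trace <- function(x, ...) {
  dur <- diff(range(x$time_s))
  cat(sprintf("<o2_trace> fish %s | %d samples | %.1f h | chamber %.2f L\n",
              attr(x, "fish_id"), nrow(x), dur / 3600,
              attr(x, "chamber_volume_l")))
  invisible(x)
}

#' Measurement/flush cycle plan
#'
#' Describes the intermittent-flow cycle structure: a closed measurement
#' phase followed by an open flush phase, repeated for the whole trial.
#' The field protocol this package targets used 6-min measurement and
#' 4-min flush phases (10-min cycles).
#'
#' @param measure_min measurement-phase length, minutes (> 0).
#' @param flush_min flush-phase length, minutes (>= 0).
#' @param trim_s seconds discarded at the start of each measurement phase
#'   before slope fitting (mixing transient); default 0.
#' @return An object of class `cycle_plan`.
#' @export
cycle_plan <- function(measure_min = 6, flush_min = 4, trim_s = 0) {
  if (measure_min <= 0) stop("measure_min must be > 0", call. = FALSE)
  if (flush_min < 0) stop("flush_min must be >= 0", call. = FALSE)
  if (trim_s < 0 || trim_s >= measure_min * 60) {
    stop("trim_s must lie in [0, measure_min * 60)", call. = FALSE)
  }
  structure(list(measure_min = measure_min, flush_min = flush_min,
                 trim_s = trim_s),
            class = "cycle_plan")
}

#' Segment a trace into measurement windows
#'
#' Tiles the trace from its first timestamp with (measure, flush) cycles and
#' returns the bounds of each complete measurement window. A trailing
#' partial cycle is dropped, so the number of windows is
#' `floor(duration / cycle_length)`. Windows are half-open `[start, end)`.
#'
#' @param trace an [o2_trace].
#' @param plan a [cycle_plan].
#' @return Data frame with columns `cycle_index`, `start_s`, `end_s`
#'   (measurement-phase bounds in seconds from trace start).
#' @export
segment_cycles <- function(trace, plan = cycle_plan()) {
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  cycle_s <- (plan$measure_min + plan$flush_min) * 60
  dt <- stats::median(diff(trace$time_s))
  t0 <- trace$time_s[1]
  duration <- trace$time_s[nrow(trace)] - t0 + dt
  n <- floor(duration / cycle_s + 1e-9)
  if (n < 1) {
    return(data.frame(cycle_index = integer(), start_s = numeric(),
                      end_s = numeric()))
  }
  start <- t0 + (seq_len(n) - 1) * cycle_s
  data.frame(cycle_index = seq_len(n),
             start_s = start,
             end_s = start + plan$measure_min * 60)
}

#' Estimate the oxygen-depletion slope in one measurement window
#'
#' Fits ordinary least squares of dissolved oxygen on time over the trimmed
#' window and reports the negated slope in mg O2 L^-1 min^-1 (positive =
#' depletion), the coefficient of determination and the mean water
#' temperature in the window. Windows with fewer than 3 samples after
#' trimming are flagged invalid.
#'
#' @param trace an [o2_trace].
#' @param start_s,end_s window bounds in seconds (half-open `[start, end)`).
#' @param trim_s seconds discarded at the window start.
#' @return A list with `slope_mg_per_l_min`, `r_squared`, `mean_temp_c`,
#'   `n`, `valid`.
#' @export
estimate_slope <- function(trace, start_s, end_s, trim_s = 0) {
  idx <- trace$time_s >= start_s + trim_s & trace$time_s < end_s
  n <- sum(idx)
  if (n < 3L) {
    return(list(slope_mg_per_l_min = NA_real_, r_squared = NA_real_,
                mean_temp_c = if (n > 0) mean(trace$temp_c[idx]) else NA_real_,
                n = n, valid = FALSE))
  }
  fit <- ls_slope(trace$time_s[idx] / 60, trace$o2_mg_per_l[idx])
  list(slope_mg_per_l_min = -fit$slope, r_squared = fit$r_squared,
       mean_temp_c = mean(trace$temp_c[idx]), n = n, valid = TRUE)
}

#' Background respiration model
#'
#' Holds the oxygen-depletion slope of the empty respirometer measured
#' before (`pre_slope`) and after (`post_slope`) the trial, and the rule
#' used to evaluate background at an arbitrary time: `"constant"` returns
#' the mean of the available slopes; `"linear"` interpolates from pre to
#' post across the trial. Negative evaluations are clamped to zero.
#'
#' @param pre_slope,post_slope background depletion slopes in
#'   mg O2 L^-1 min^-1; either (but not both) may be `NA`.
#' @param interpolation `"linear"` (default) or `"constant"`.
#' @return An object of class `background_model`.
#' @export
background_model <- function(pre_slope = NA_real_, post_slope = NA_real_,
                             interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  if (is.na(pre_slope) && is.na(post_slope)) {
    stop("at least one of pre_slope and post_slope is required", call. = FALSE)
  }
  structure(list(pre_slope = pre_slope, post_slope = post_slope,
                 interpolation = interpolation),
            class = "background_model")
}

#' Evaluate background respiration at a time point
#'
#' @param model a [background_model].
#' @param t_s time in seconds from trial start.
#' @param trial_duration_s total trial duration in seconds (needed for
#'   linear interpolation).
#' @return Background depletion slope in mg O2 L^-1 min^-1, clamped at 0.
#' @export
evaluate_background <- function(model, t_s, trial_duration_s) {
  pre <- model$pre_slope
  post <- model$post_slope
  if (is.na(pre)) pre <- post
  if (is.na(post)) post <- pre
  val <- if (model$interpolation == "constant") {
    rep(mean(c(pre, post)), length(t_s))
  } else {
    pre + (post - pre) * t_s / trial_duration_s
  }
  pmax(val, 0)
}

#' Fit a background model from empty-chamber traces
#'
#' Estimates the mean measurement-phase depletion slope of pre- and
#' post-trial empty-respirometer traces and packages them as a
#' [background_model].
#'
#' @param pre_trace,post_trace [o2_trace] objects from the empty chamber;
#'   either may be `NULL`.
#' @param plan a [cycle_plan].
#' @param interpolation passed to [background_model()].
#' @return A [background_model].
#' @export
fit_background <- function(pre_trace = NULL, post_trace = NULL,
                           plan = cycle_plan(),
                           interpolation = c("linear", "constant")) {
  mean_slope <- function(trace) {
    if (is.null(trace)) return(NA_real_)
    win <- segment_cycles(trace, plan)
    if (nrow(win) == 0L) {
      # shorter than one full cycle: fit the whole record
      s <- estimate_slope(trace, trace$time_s[1],
                          trace$time_s[nrow(trace)] + 1, plan$trim_s)
      return(s$slope_mg_per_l_min)
    }
    slopes <- vapply(seq_len(nrow(win)), function(i) {
      estimate_slope(trace, win$start_s[i], win$end_s[i],
                     plan$trim_s)$slope_mg_per_l_min
    }, numeric(1))
    mean(slopes, na.rm = TRUE)
  }
  background_model(mean_slope(pre_trace), mean_slope(post_trace),
                   match.arg(interpolation))
}

#' Mass-specific oxygen consumption rate (per measurement phase)
#'
#' Computes the background-corrected, mass-specific oxygen consumption rate
#' from the fish and background depletion slopes:
#' \deqn{\dot{M}O_2 = \frac{\Delta[O_2]_{fish}(V_{chamber} - Mass)
#'   - \Delta[O_2]_{background} V_{chamber}}{Mass}}
#' with slopes in mg O2 L^-1 min^-1, volume in litres and mass in kg
#' (fish volume is taken as its mass at density 1). The result is in
#' mg O2 kg^-1 min^-1 and can be negative only when background exceeds the
#' fish signal.
#'
#' @param slope_fish fish-chamber depletion slope, mg O2 L^-1 min^-1.
#' @param slope_background empty-chamber depletion slope, same units.
#' @param chamber_volume_l chamber volume, litres.
#' @param mass_kg fish body mass, kg; must satisfy
#'   `0 < mass_kg < chamber_volume_l`.
#' @return Numeric MO2 in mg O2 kg^-1 min^-1 (vectorised over slopes).
#' @export
compute_mo2 <- function(slope_fish, slope_background, chamber_volume_l,
                        mass_kg) {
  stopifnot_scalar(chamber_volume_l, "chamber_volume_l")
  stopifnot_scalar(mass_kg, "mass_kg")
  if (mass_kg <= 0 || mass_kg >= chamber_volume_l) {
    stop("mass_kg must satisfy 0 < mass_kg < chamber_volume_l", call. = FALSE)
  }
  (slope_fish * (chamber_volume_l - mass_kg) -
     slope_background * chamber_volume_l) / mass_kg
}

#' Build a per-cycle MO2 series from a raw trace
#'
#' Orchestrates segmentation, slope estimation, background correction and
#' the mass-specific MO2 calculation, yielding one MO2 value per accepted
#' measurement phase. Windows that are invalid (fewer than 3 samples after
#' trimming) or fall below the optional r-squared floor are excluded.
#'
#' @param trace an [o2_trace].
#' @param plan a [cycle_plan].
#' @param background a [background_model]; defaults to zero background.
#' @param mass_kg fish body mass in kg.
#' @param fish_id identifier; defaults to the trace attribute.
#' @param r2_floor minimum r-squared for a window to be kept (default 0,
#'   i.e. all windows kept).
#' @return An object of class `mo2_series`: a data frame with columns
#'   `cycle_index`, `mid_time_s`, `mo2`, `mean_temp_c`, `r_squared`,
#'   `flagged_negative`, plus attributes `fish_id`, `mass_kg`,
#'   `chamber_volume_l` and `background_fraction` (mean background slope
#'   over mean fish slope).
#' @export
build_mo2_series <- function(trace, plan = cycle_plan(),
                             background = background_model(0, 0),
                             mass_kg, fish_id = attr(trace, "fish_id"),
                             r2_floor = 0) {
  stopifnot_scalar(mass_kg, "mass_kg")
  win <- segment_cycles(trace, plan)
  if (nrow(win) == 0L) stop("trace shorter than one full cycle", call. = FALSE)
  dt <- stats::median(diff(trace$time_s))
  duration <- trace$time_s[nrow(trace)] - trace$time_s[1] + dt
  rows <- lapply(seq_len(nrow(win)), function(i) {
    s <- estimate_slope(trace, win$start_s[i], win$end_s[i], plan$trim_s)
    if (!s$valid) return(NULL)
    if (s$r_squared < r2_floor) return(NULL)
    mid <- (win$start_s[i] + win$end_s[i]) / 2
    bg <- evaluate_background(background, mid - trace$time_s[1], duration)
    data.frame(cycle_index = win$cycle_index[i], mid_time_s = mid,
               mo2 = compute_mo2(s$slope_mg_per_l_min, bg,
                                 attr(trace, "chamber_volume_l"), mass_kg),
               mean_temp_c = s$mean_temp_c, r_squared = s$r_squared,
               slope_fish = s$slope_mg_per_l_min, slope_background = bg)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no valid measurement windows", call. = FALSE)
  out <- do.call(rbind, rows)
  out$flagged_negative <- out$mo2 < 0
  mean_fish <- mean(out$slope_fish)
  attr(out, "fish_id") <- fish_id
  attr(out, "mass_kg") <- mass_kg
  attr(out, "chamber_volume_l") <- attr(trace, "chamber_volume_l")
  attr(out, "background_fraction") <-
    if (mean_fish > 0) mean(out$slope_background) / mean_fish else NA_real_
  class(out) <- c("mo2_series", "data.frame")
  out
}

#' @export
print.mo2_series <- function(x, ...) {
  cat(sprintf(
    "<mo2_series> fish %s | %d cycles | MO2 %.2f-%.2f mg O2 kg-1 min-1 | bg %.2f%%\n",
    attr(x, "fish_id"), nrow(x), min(x$mo2), max(x$mo2),
    100 * attr(x, "background_fraction")))
  invisible(x)
}

#' Read a raw trace from delimited text
#'
#' Reads a chamber log written as CSV with columns `time_s`, `o2_mg_per_l`,
#' `temp_c` and optionally `phase`. Other sensor dialects can be ingested
#' by supplying `col_map`, a named character vector mapping the standard
#' names to the file's headers, e.g.
#' `c(time_s = "Time", o2_mg_per_l = "Oxygen", temp_c = "Temp")`.
#'
#' @param path file path.
#' @param chamber_volume_l chamber volume in litres.
#' @param fish_id fish identifier.
#' @param col_map optional named character vector of column mappings.
#' @param sep field separator (default comma).
#' @return An [o2_trace].
#' @export
read_trace <- function(path, chamber_volume_l = 2, fish_id = NA_character_,
                       col_map = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        stop(sprintf("column '%s' not found in %s", col_map[[std]], path),
             call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  keep <- intersect(c("time_s", "o2_mg_per_l", "temp_c", "phase"), names(raw))
  o2_trace(raw[keep], chamber_volume_l = chamber_volume_l, fish_id = fish_id)
}

#' Write a trace to delimited text
#'
#' @param trace an [o2_trace].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
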