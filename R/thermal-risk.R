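#' Packaged site context table
#'
#' Returns the per-watershed environmental context for the four Oregon
#' study streams: NorWeST maximum weekly maximum temperature (MWMT)
#' estimates for the 2002-2011 baseline and the 2080 projection, the
#' observed ambient temperature summary, and the three treatment
#' temperatures (Ambient mean, Max, Climate).
#'
#' @param path optional path to an alternative site CSV with the same
#'   columns.
#' @return Data frame with one row per watershed.
#' @export
site_context <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "site_context.csv",
                        package = "streamresp", mustWork = TRUE)
  }
  ctx <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("watershed", "mwmt_baseline_c", "mwmt_2080_c", "ambient_mean_c",
           "max_treatment_c", "climate_treatment_c")
  if (!all(req %in% names(ctx))) {
    stop("site context file must contain columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  bad <- ctx$climate_treatment_c <= ctx$max_treatment_c |
    ctx$mwmt_2080_c <= ctx$mwmt_baseline_c
  if (any(bad)) {
    stop("invalid site context: Climate must exceed Max and 2080 MWMT must exceed baseline",
         call. = FALSE)
  }
  ctx
}

#' Thermal safety margin
#'
#' The buffer between an individual's critical thermal maximum and the
#' maximum temperature of its habitat: `TSM = CTmax - MWMT`. Negative
#' values indicate lethal exposure.
#'
#' @param ctmax_c critical thermal maximum, deg C (vectorised).
#' @param mwmt_c maximum weekly maximum stream temperature, deg C.
#' @return TSM in deg C.
#' @export
thermal_safety_margin <- function(ctmax_c, mwmt_c) {
  ctmax_c - mwmt_c
}

#' Temperature at which factorial aerobic scope hits a threshold (T-pejus)
#'
#' Fits a least-squares line `FAS = a + b * T` to per-fish factorial
#' aerobic scope against mean test temperature (pooled across treatments
#' within a watershed) and inverts it at `threshold` (default FAS = 3, the
#' level proposed for a subadult salmonid to thrive). When the fitted
#' slope is non-negative - FAS stable or rising with temperature - T-pejus
#' is undefined rather than extrapolated.
#'
#' @param temp_c mean test temperature per fish, deg C.
#' @param fas factorial aerobic scope per fish.
#' @param threshold FAS threshold defining T-pejus (default 3).
#' @return An object of class `tpejus_fit`: a list with `tpejus_c` (or
#'   `NA`), `defined`, `reason`, `slope`, `intercept`, `extrapolated`
#'   (whether the crossing lies outside the observed temperature range),
#'   `n`, `threshold`.
#' @export
fit_tpejus <- function(temp_c, fas, threshold = 3) {
  if (length(temp_c) != length(fas)) {
    stop("temp_c and fas must have equal length", call. = FALSE)
  }
  ok <- is.finite(temp_c) & is.finite(fas)
  temp_c <- temp_c[ok]; fas <- fas[ok]
  if (length(fas) < 6L || length(unique(temp_c)) < 2L) {
    stop("T-pejus fit needs >= 6 points spanning >= 2 temperatures",
         call. = FALSE)
  }
  fit <- stats::lm(fas ~ temp_c)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (b >= -1e-9) {  # flat within numerical noise counts as non-declining
    return(structure(list(tpejus_c = NA_real_, defined = FALSE,
                          reason = "FAS stable or rising with temperature",
                          slope = b, intercept = a, extrapolated = NA,
                          n = length(fas), threshold = threshold),
                     class = "tpejus_fit"))
  }
  tp <- (threshold - a) / b
  structure(list(tpejus_c = tp, defined = TRUE, reason = NA_character_,
                 slope = b, intercept = a,
                 extrapolated = tp > max(temp_c) + 1e-8 ||
                   tp < min(temp_c) - 1e-8,
                 n = length(fas), threshold = threshold),
            class = "tpejus_fit")
}

#' @export
print.tpejus_fit <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("T-pejus = %.2f degC at FAS = %g (slope %.3f/degC%s)\n",
                x$tpejus_c, x$threshold, x$slope,
                if (isTRUE(x$extrapolated)) ", extrapolated" else ""))
  } else {
    cat(sprintf("T-pejus undefined: %s\n", x$reason))
  }
  invisible(x)
}

#' Functional warming tolerance
#'
#' The buffer between the temperature at which performance ceases to be
#' optimal and the habitat's maximum temperature: `WT = T-pejus - MWMT`.
#' Undefined T-pejus propagates to an undefined WT.
#'
#' @param tpejus_c T-pejus, deg C (may be `NA`).
#' @param mwmt_c maximum weekly maximum stream temperature, deg C.
#' @return WT in deg C, or `NA`.
#' @export
warming_tolerance <- function(tpejus_c, mwmt_c) {
  tpejus_c - mwmt_c
}

#' Critical thermal maximum from a heating-ramp trial
#'
#' Reads the loss-of-equilibrium (LOE) temperature off the recorded ramp
#' log at the observed LOE time and reports the realised heating rate per
#' 3-minute window.
#'
#' @param ramp_log data frame with `time_min` and `temp_c` covering the
#'   trial.
#' @param loe_time_min time of loss of equilibrium, minutes from ramp
#'   start.
#' @param fish_id identifier.
#' @return An object of class `ctmax_record` with `loe_temp_c`,
#'   `loe_time_min`, `start_temp_c`, `ramp_rate_c_per_min` (mean realised),
#'   `rate_per_3min` (mean, min, max across 3-min windows) and the log.
#' @export
ctmax_from_trial <- function(ramp_log, loe_time_min, fish_id = NA_character_) {
  if (!all(c("time_min", "temp_c") %in% names(ramp_log))) {
    stop("ramp_log must have columns time_min, temp_c", call. = FALSE)
  }
  if (loe_time_min < min(ramp_log$time_min) ||
      loe_time_min > max(ramp_log$time_min)) {
    stop("loe_time_min lies outside the ramp log", call. = FALSE)
  }
  tfun <- stats::approxfun(ramp_log$time_min, ramp_log$temp_c, rule = 1)
  loe_temp <- tfun(loe_time_min)
  grid <- seq(min(ramp_log$time_min),
              min(max(ramp_log$time_min), loe_time_min), by = 3)
  rates <- if (length(grid) >= 2) diff(tfun(grid)) else numeric(0)
  structure(list(fish_id = fish_id, loe_temp_c = loe_temp,
                 loe_time_min = loe_time_min,
                 start_temp_c = ramp_log$temp_c[1],
                 ramp_rate_c_per_min =
                   if (loe_time_min > 0)
                     (loe_temp - ramp_log$temp_c[1]) / loe_time_min
                   else NA_real_,
                 rate_per_3min = if (length(rates) > 0) {
                   c(mean = mean(rates), min = min(rates), max = max(rates))
                 } else c(mean = NA_real_, min = NA_real_, max = NA_real_),
                 ramp_log = ramp_log),
            class = "ctmax_record")
}

#' @export
print.ctmax_record <- function(x, ...) {
  cat(sprintf("<ctmax_record> fish %s | LOE %.2f degC at %.1f min\n",
              x$fish_id, x$loe_temp_c, x$loe_time_min))
  invisible(x)
}

#' Per-watershed thermal risk metrics
#'
#' Combines CT-max records, per-fish aerobic-scope traits and the site
#' context into the climate-implication summary: group mean thermal safety
#' margin (TSM), T-pejus from the pooled FAS-temperature regression, and
#' functional warming tolerance (WT), each under the baseline and 2080
#' MWMT horizons.
#'
#' @param ctmax_df data frame with `fish_id`, `watershed`, `loe_temp_c`
#'   (one row per CT-max-tested fish).
#' @param traits_df data frame with `fish_id`, `watershed`, `fas`,
#'   `mean_temp_c` (one row per fish, all treatments).
#' @param context data frame from [site_context()].
#' @param fas_threshold FAS level defining T-pejus (default 3).
#' @return Data frame with one row per watershed x horizon:
#'   `watershed`, `horizon`, `mwmt_c`, `mean_ctmax_c`, `tsm_c`,
#'   `tsm_lethal`, `tpejus_c`, `wt_c`, `tpejus_defined`,
#'   `tpejus_extrapolated`.
#' @export
risk_metrics <- function(ctmax_df, traits_df, context = site_context(),
                         fas_threshold = 3) {
  rows <- list()
  for (w in unique(traits_df$watershed)) {
    ctx <- context[context$watershed == w, ]
    if (nrow(ctx) != 1L) stop("no site context for watershed ", w,
                              call. = FALSE)
    cm <- ctmax_df[ctmax_df$watershed == w, , drop = FALSE]
    tw <- traits_df[traits_df$watershed == w, , drop = FALSE]
    tp <- tryCatch(fit_tpejus(tw$mean_temp_c, tw$fas, fas_threshold),
                   error = function(e) NULL)
    for (h in c("baseline", "2080")) {
      mwmt <- if (h == "baseline") ctx$mwmt_baseline_c else ctx$mwmt_2080_c
      mean_ct <- if (nrow(cm) > 0) mean(cm$loe_temp_c) else NA_real_
      tsm <- thermal_safety_margin(mean_ct, mwmt)
      tpejus <- if (!is.null(tp) && tp$defined) tp$tpejus_c else NA_real_
      rows[[paste(w, h)]] <- data.frame(
        watershed = w, horizon = h, mwmt_c = mwmt,
        mean_ctmax_c = mean_ct, tsm_c = tsm,
        tsm_lethal = !is.na(tsm) && tsm < 0,
        tpejus_c = tpejus,
        wt_c = warming_tolerance(tpejus, mwmt),
        tpejus_defined = !is.null(tp) && tp$defined,
        tpejus_extrapolated = if (!is.null(tp) && tp$defined)
          tp$extrapolated else NA,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}
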