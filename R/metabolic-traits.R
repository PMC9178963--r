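#' Standard metabolic rate from an MO2 series
#'
#' SMR is estimated as the mean of the lowest 20% of all recorded per-cycle
#' MO2 values over the whole trial (the recovery period included), with the
#' subset size `max(1, round(0.2 * N))` using half-up rounding. The
#' temperatures of those same cycles are averaged to give the temperature
#' at which SMR applies.
#'
#' @param series an `mo2_series` from [build_mo2_series()] (or any data
#'   frame with `mo2` and `mean_temp_c` columns); at least 5 entries.
#' @return A list with `smr`, `smr_temp_c`, `smr_n`.
#' @export
estimate_smr <- function(series) {
  n <- nrow(series)
  if (is.null(n) || n < 5L) {
    stop("SMR estimation needs at least 5 MO2 values", call. = FALSE)
  }
  k <- max(1L, as.integer(half_up(0.2 * n)))
  ord <- order(series$mo2)[seq_len(k)]
  list(smr = mean(series$mo2[ord]),
       smr_temp_c = mean(series$mean_temp_c[ord]),
       smr_n = k)
}

#' Maximum metabolic rate from an MO2 series
#'
#' MMR is the highest per-cycle MO2 in the trial; with an exhaustive chase
#' immediately before the trial this is normally the first measurement
#' phase. Its timestamp defines time zero for the recovery metrics.
#'
#' @param series an `mo2_series`; non-empty.
#' @return A list with `mmr`, `mmr_time_s`, `mmr_temp_c`, `mmr_cycle`.
#' @export
estimate_mmr <- function(series) {
  if (nrow(series) == 0L) stop("empty MO2 series", call. = FALSE)
  i <- which.max(series$mo2)
  list(mmr = series$mo2[i], mmr_time_s = series$mid_time_s[i],
       mmr_temp_c = series$mean_temp_c[i],
       mmr_cycle = series$cycle_index[i])
}

#' Absolute and factorial aerobic scope
#'
#' @param smr standard metabolic rate (> 0).
#' @param mmr maximum metabolic rate.
#' @return A list with `aas` (MMR - SMR) and `fas` (MMR / SMR).
#' @export
aerobic_scope <- function(smr, mmr) {
  if (any(smr <= 0)) stop("smr must be > 0", call. = FALSE)
  list(aas = mmr - smr, fas = mmr / smr)
}

#' Routine metabolic rate by temperature bin
#'
#' Averages post-recovery MO2 values (those recorded after the end of
#' EPOC) within temperature bins. Bins are `bin_width_c` wide with centres
#' on integer multiples of the width; bins holding fewer than 3
#' measurements for a fish are dropped.
#'
#' @param series an `mo2_series`.
#' @param epoc_end_s end of EPOC in seconds from trial start; only entries
#'   after this time contribute.
#' @param bin_width_c temperature bin width, deg C (default 1).
#' @param min_n minimum measurements per retained bin (default 3).
#' @return Data frame with columns `fish_id`, `temp_bin_c`, `rmr`, `n`.
#' @export
estimate_rmr <- function(series, epoc_end_s, bin_width_c = 1, min_n = 3) {
  if (bin_width_c <= 0) stop("bin_width_c must be > 0", call. = FALSE)
  fid <- attr(series, "fish_id")
  if (is.null(fid)) fid <- NA_character_
  post <- series[series$mid_time_s > epoc_end_s, , drop = FALSE]
  if (nrow(post) == 0L) {
    warning("no post-EPOC entries; returning empty RMR table", call. = FALSE)
    return(data.frame(fish_id = character(), temp_bin_c = numeric(),
                      rmr = numeric(), n = integer()))
  }
  bin <- half_up(post$mean_temp_c / bin_width_c) * bin_width_c
  agg <- stats::aggregate(post$mo2, by = list(temp_bin_c = bin),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(fish_id = fid, temp_bin_c = agg$temp_bin_c,
                    rmr = agg$x[, 1], n = as.integer(agg$x[, 2]),
                    stringsAsFactors = FALSE)
  out <- out[out$n >= min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Q10 temperature coefficient
#'
#' The multiplicative factor by which a metabolic rate changes per 10 deg C:
#' `Q10 = (R2/R1)^(10/(T2 - T1))`. A value of 1 indicates temperature
#' independence.
#'
#' @param r1,r2 rates at temperatures `t1` and `t2` (both > 0).
#' @param t1,t2 temperatures, deg C (`t1 != t2`).
#' @return An object of class `q10_result`: a list with `q10`, `r1`, `r2`,
#'   `t1`, `t2`.
#' @export
q10 <- function(r1, r2, t1, t2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("rates must be > 0", call. = FALSE)
  if (any(t1 == t2)) stop("t1 and t2 must differ", call. = FALSE)
  structure(list(q10 = (r2 / r1)^(10 / (t2 - t1)),
                 r1 = r1, r2 = r2, t1 = t1, t2 = t2),
            class = "q10_result")
}

#' @export
print.q10_result <- function(x, ...) {
  cat(sprintf("Q10 = %.3f  (R %.3f -> %.3f over %.1f -> %.1f degC)\n",
              x$q10, x$r1, x$r2, x$t1, x$t2))
  invisible(x)
}

#' Fulton's condition factor
#'
#' `K = 100000 * M / L^3` with mass in grams and fork length in
#' millimetres; values near 1 indicate typical condition for stream
#' salmonids.
#'
#' @param mass_g body mass, grams (> 0).
#' @param fork_length_mm fork length, millimetres (> 0).
#' @return Numeric K (vectorised).
#' @export
condition_factor <- function(mass_g, fork_length_mm) {
  if (any(mass_g <= 0) || any(fork_length_mm <= 0)) {
    stop("mass and fork length must be > 0", call. = FALSE)
  }
  1e5 * mass_g / fork_length_mm^3
}

#' Allometric mass-scaling check
#'
#' Regresses natural-log whole-animal oxygen consumption on natural-log
#' body mass across a cohort and reports the scaling exponent with its 95%
#' confidence interval. When the interval contains 1 the mass-specific
#' formulation is considered adequate (no allometric mass correction
#' needed).
#'
#' @param rate_whole whole-animal rates (e.g. mg O2 min^-1), one per fish.
#' @param mass_kg body masses, kg.
#' @param level confidence level (default 0.95).
#' @return A list with `slope`, `ci` (length-2), `mass_correction_needed`
#'   (logical), `n`.
#' @export
mass_scaling_check <- function(rate_whole, mass_kg, level = 0.95) {
  if (length(rate_whole) != length(mass_kg)) {
    stop("rate and mass vectors must have equal length", call. = FALSE)
  }
  if (length(unique(mass_kg)) < 3L) {
    stop("need at least 3 fish with distinct masses", call. = FALSE)
  }
  fit <- stats::lm(log(rate_whole) ~ log(mass_kg))
  ci <- stats::confint(fit, "log(mass_kg)", level = level)
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope, ci = as.numeric(ci),
       mass_correction_needed = !(ci[1] <= 1 && 1 <= ci[2]),
       n = length(mass_kg))
}

#' Derive the full per-fish trait set
#'
#' Convenience wrapper combining [estimate_smr()], [estimate_mmr()],
#' [aerobic_scope()] and [condition_factor()] for one MO2 series.
#'
#' @param series an `mo2_series`.
#' @param mass_g body mass in grams.
#' @param fork_length_mm fork length in millimetres.
#' @return An object of class `trait_set`: a one-row data frame with
#'   `fish_id`, `smr`, `smr_temp_c`, `smr_n`, `mmr`, `mmr_time_s`,
#'   `mmr_temp_c`, `aas`, `fas`, `condition_k`, `mean_temp_c`.
#' @export
derive_traits <- function(series, mass_g, fork_length_mm) {
  s <- estimate_smr(series)
  m <- estimate_mmr(series)
  sc <- aerobic_scope(s$smr, m$mmr)
  out <- data.frame(fish_id = attr(series, "fish_id"),
                    smr = s$smr, smr_temp_c = s$smr_temp_c, smr_n = s$smr_n,
                    mmr = m$mmr, mmr_time_s = m$mmr_time_s,
                    mmr_temp_c = m$mmr_temp_c,
                    aas = sc$aas, fas = sc$fas,
                    condition_k = condition_factor(mass_g, fork_length_mm),
                    mean_temp_c = mean(series$mean_temp_c),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_set", "data.frame")
  out
}
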