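#' Ground-truth parameters for one simulated fish
#'
#' Collects the generative parameters behind a simulated respirometry
#' trial: the standard metabolic rate at a reference temperature, its Q10
#' temperature sensitivity, the excess post-exercise oxygen consumption
#' (EPOC) decay, and the critical-thermal-maximum distribution.
#'
#' @param fish_id identifier.
#' @param mass_g body mass, grams (> 0).
#' @param fork_length_mm fork length, millimetres (> 0).
#' @param smr_ref standard metabolic rate at `t_ref_c`,
#'   mg O2 kg^-1 min^-1 (> 0).
#' @param t_ref_c reference temperature for `smr_ref`, deg C.
#' @param q10_true Q10 temperature coefficient (>= 1).
#' @param epoc_magnitude excess MO2 above SMR at the moment the fish enters
#'   the chamber, mg O2 kg^-1 min^-1 (>= 0).
#' @param epoc_rate_k exponential decay constant of the EPOC excess,
#'   per minute (> 0).
#' @param ctmax_true_mean,ctmax_true_sd mean and sd of the
#'   loss-of-equilibrium temperature, deg C.
#' @return An object of class `sim_fish_truth`.
#' @export
sim_fish_truth <- function(fish_id, mass_g = 22.8, fork_length_mm = 130.2,
                           smr_ref = 1.5, t_ref_c = 18, q10_true = 2,
                           epoc_magnitude = 8, epoc_rate_k = 0.07,
                           ctmax_true_mean = 30, ctmax_true_sd = 0.3) {
  if (mass_g <= 0) stop("mass_g must be > 0", call. = FALSE)
  if (fork_length_mm <= 0) stop("fork_length_mm must be > 0", call. = FALSE)
  if (smr_ref <= 0) stop("smr_ref must be > 0", call. = FALSE)
  if (q10_true < 1) stop("q10_true must be >= 1", call. = FALSE)
  if (epoc_magnitude < 0) stop("epoc_magnitude must be >= 0", call. = FALSE)
  if (epoc_rate_k <= 0) stop("epoc_rate_k must be > 0", call. = FALSE)
  structure(list(fish_id = fish_id, mass_g = mass_g,
                 fork_length_mm = fork_length_mm, smr_ref = smr_ref,
                 t_ref_c = t_ref_c, q10_true = q10_true,
                 epoc_magnitude = epoc_magnitude, epoc_rate_k = epoc_rate_k,
                 ctmax_true_mean = ctmax_true_mean,
                 ctmax_true_sd = ctmax_true_sd),
            class = "sim_fish_truth")
}

#' Simulated trial design
#'
#' Structural and noise parameters of one intermittent-flow trial. The
#' defaults mirror the stream-side protocol this package targets: 2-L
#' chambers, 6-min measurement + 4-min flush cycles, 18-24 h overnight
#' trials, and background respiration at a small fraction of fish
#' respiration. Probe sampling at 1 Hz.
#'
#' @param duration_h trial duration, hours; must give a whole number of
#'   cycles.
#' @param measure_min,flush_min cycle phase lengths, minutes.
#' @param sample_interval_s probe sampling interval, seconds.
#' @param chamber_volume_l chamber volume, litres.
#' @param noise_sd Gaussian probe noise sd on recorded oxygen, mg/L.
#' @param background_fraction background depletion as a fraction of mean
#'   fish depletion; ignored when `background_slope` is given.
#' @param background_slope absolute background depletion slope,
#'   mg O2 L^-1 min^-1, or `NULL` to derive it from
#'   `background_fraction`.
#' @param flush_tau_min time constant of the exponential return toward air
#'   saturation during flushing, minutes.
#' @param o2_saturation_mg_per_l air-saturation ceiling, mg/L.
#' @param start_hour clock hour at which the trial starts (used by diurnal
#'   temperature profiles).
#' @param seed RNG seed for this trial, or `NULL`.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(duration_h = 24, measure_min = 6, flush_min = 4,
                         sample_interval_s = 1, chamber_volume_l = 2,
                         noise_sd = 0.02, background_fraction = 0.01,
                         background_slope = NULL, flush_tau_min = 1,
                         o2_saturation_mg_per_l = 9, start_hour = 9.5,
                         seed = NULL) {
  if (chamber_volume_l <= 0) stop("chamber_volume_l must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cycle_min <- measure_min + flush_min
  n_cycles <- duration_h * 60 / cycle_min
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop(sprintf(
      "trial duration of %g h is not a whole number of %g-min measurement:flush cycles",
      duration_h, cycle_min), call. = FALSE)
  }
  structure(list(duration_h = duration_h, measure_min = measure_min,
                 flush_min = flush_min, sample_interval_s = sample_interval_s,
                 chamber_volume_l = chamber_volume_l, noise_sd = noise_sd,
                 background_fraction = background_fraction,
                 background_slope = background_slope,
                 flush_tau_min = flush_tau_min,
                 o2_saturation_mg_per_l = o2_saturation_mg_per_l,
                 start_hour = start_hour, seed = seed),
            class = "trial_design")
}

#' Temperature profiles
#'
#' `constant_profile()` returns a flat temperature function of time;
#' `diurnal_profile()` returns a sinusoid with a given mean, half-range
#' amplitude and clock hour of the daily peak (stream temperatures in the
#' target systems peaked between 15:30 and 18:00).
#'
#' @param temp_c constant temperature, deg C.
#' @return A function mapping seconds-from-trial-start to deg C.
#' @export
constant_profile <- function(temp_c) {
  force(temp_c)
  function(t_s) rep_len(temp_c, length(t_s))
}

#' @rdname constant_profile
#' @param mean_c daily mean temperature, deg C.
#' @param amplitude_c half-range of the diurnal cycle, deg C.
#' @param peak_hour clock hour of the daily maximum (default 16.75,
#'   i.e. 16:45).
#' @param start_hour clock hour corresponding to `t_s = 0`.
#' @export
diurnal_profile <- function(mean_c, amplitude_c = 1.5, peak_hour = 16.75,
                            start_hour = 9.5) {
  force(mean_c); force(amplitude_c); force(peak_hour); force(start_hour)
  function(t_s) {
    hour <- start_hour + t_s / 3600
    mean_c + amplitude_c * cos(2 * pi * (hour - peak_hour) / 24)
  }
}

# Coerce a profile given as a function or a (time_s, temp_c) data frame to
# a function, validating coverage of the whole trial.
as_temp_profile <- function(profile, duration_s) {
  if (is.function(profile)) {
    probe <- profile(c(0, duration_s))
    if (any(!is.finite(probe))) {
      stop("temperature profile is not defined over the whole trial",
           call. = FALSE)
    }
    return(profile)
  }
  if (is.data.frame(profile) && all(c("time_s", "temp_c") %in% names(profile))) {
    if (max(profile$time_s) < duration_s) {
      stop("temperature profile shorter than trial", call. = FALSE)
    }
    f <- stats::approxfun(profile$time_s, profile$temp_c, rule = 1)
    return(f)
  }
  stop("profile must be a function or a data frame with time_s, temp_c",
       call. = FALSE)
}

#' Instantaneous simulated MO2
#'
#' The generating mass-specific oxygen consumption at time `t_min` minutes
#' after the fish enters the chamber: SMR scaled by Q10 to the current
#' temperature plus the exponentially decaying EPOC excess.
#'
#' @param truth a [sim_fish_truth].
#' @param t_min minutes from trial start.
#' @param temp_c water temperature at `t_min`, deg C.
#' @return MO2 in mg O2 kg^-1 min^-1 (vectorised).
#' @export
true_mo2 <- function(truth, t_min, temp_c) {
  truth$smr_ref * truth$q10_true^((temp_c - truth$t_ref_c) / 10) +
    truth$epoc_magnitude * exp(-truth$epoc_rate_k * t_min)
}

#' Simulate one intermittent-flow respirometry trial
#'
#' Generates a chamber oxygen trace for one fish: during each measurement
#' phase the chamber oxygen declines at the rate implied by the fish's
#' instantaneous MO2 (inverted through the mass-specific rate equation)
#' plus background respiration; each flush phase relaxes oxygen
#' exponentially back toward air saturation. Gaussian probe noise is added
#' to the recorded samples only. Identical seeds give identical traces.
#'
#' @param truth a [sim_fish_truth].
#' @param design a [trial_design].
#' @param profile temperature profile: a function of seconds, or a data
#'   frame with `time_s`, `temp_c` covering the trial.
#' @return A list with `trace` (an [o2_trace] with phase labels) and
#'   `truth` (the input truth augmented with the realised background slope
#'   and the mean generating MO2).
#' @export
simulate_trial <- function(truth, design = trial_design(),
                           profile = constant_profile(truth$t_ref_c)) {
  dt <- design$sample_interval_s
  duration_s <- design$duration_h * 3600
  profile <- as_temp_profile(profile, duration_s)
  times <- seq(0, duration_s - dt, by = dt)
  temp <- profile(times)
  if (any(!is.finite(temp))) {
    stop("temperature profile shorter than trial", call. = FALSE)
  }
  mass_kg <- truth$mass_g / 1000
  vol <- design$chamber_volume_l
  if (mass_kg >= vol) stop("fish mass exceeds chamber volume", call. = FALSE)

  mo2 <- true_mo2(truth, times / 60, temp)
  fish_slope <- mo2 * mass_kg / (vol - mass_kg)   # mg/L/min; density-1 displacement
  # background_slope is what an EMPTY chamber measures (microbial mass rate
  # over volume V); with the fish displacing its volume, the same microbes
  # deplete the remaining (V - m) litres faster by V / (V - m)
  bg_empty <- if (!is.null(design$background_slope)) {
    design$background_slope
  } else {
    design$background_fraction * mean(fish_slope)
  }
  bg_slope <- bg_empty * vol / (vol - mass_kg)

  cycle_s <- (design$measure_min + design$flush_min) * 60
  measure_s <- design$measure_min * 60
  n_cycles <- as.integer(round(duration_s / cycle_s))
  dt_min <- dt / 60
  sat <- design$o2_saturation_mg_per_l

  o2 <- numeric(length(times))
  in_cycle <- times %% cycle_s
  phase <- ifelse(in_cycle < measure_s, "measure", "flush")
  cur <- sat
  for (ci in seq_len(n_cycles)) {
    base <- (ci - 1) * cycle_s
    m_idx <- which(times >= base & times < base + measure_s)
    f_idx <- which(times >= base + measure_s & times < base + cycle_s)
    inc <- (fish_slope[m_idx] + bg_slope) * dt_min
    o2[m_idx] <- cur - (cumsum(inc) - inc[1])
    cur <- o2[m_idx[length(m_idx)]] - inc[length(inc)]
    if (length(f_idx) > 0) {
      rel <- exp(-(seq_along(f_idx)) * dt_min / design$flush_tau_min)
      o2[f_idx] <- sat + (cur - sat) * rel
      cur <- o2[f_idx[length(f_idx)]]
    }
  }
  if (design$noise_sd > 0) {
    o2 <- o2 + with_seed(design$seed,
                         stats::rnorm(length(o2), 0, design$noise_sd))
  }
  o2 <- pmax(o2, 0)

  trace <- o2_trace(data.frame(time_s = times, o2_mg_per_l = o2,
                               temp_c = temp, phase = phase),
                    chamber_volume_l = vol, fish_id = truth$fish_id)
  truth_out <- truth
  truth_out$background_slope <- bg_empty
  truth_out$background_fraction_realised <- bg_empty / mean(fish_slope)
  truth_out$mean_true_mo2 <- mean(mo2)
  list(trace = trace, truth = truth_out)
}

#' Simulate an empty-chamber (background) trace
#'
#' Generates a short trace of the empty respirometer with a constant
#' background depletion slope plus probe noise, for use with
#' [fit_background()].
#'
#' @param bg_slope background depletion slope, mg O2 L^-1 min^-1.
#' @param design a [trial_design] (cycle structure and noise are reused).
#' @param n_cycles number of measurement:flush cycles to generate.
#' @param temp_c constant water temperature, deg C.
#' @param seed RNG seed.
#' @return An [o2_trace] with `fish_id = NA`.
#' @export
simulate_background_trace <- function(bg_slope, design = trial_design(),
                                      n_cycles = 3, temp_c = 18,
                                      seed = NULL) {
  d <- design
  d$duration_h <- n_cycles * (d$measure_min + d$flush_min) / 60
  d$seed <- seed
  d$background_slope <- bg_slope
  ghost <- sim_fish_truth(fish_id = NA_character_, mass_g = 1e-6,
                          smr_ref = 1e-9, t_ref_c = temp_c, q10_true = 1,
                          epoc_magnitude = 0, epoc_rate_k = 1)
  sim <- simulate_trial(ghost, d, constant_profile(temp_c))
  sim$trace
}

#' Simulate a critical-thermal-maximum trial
#'
#' Draws a loss-of-equilibrium (LOE) temperature from
#' Normal(`ctmax_true_mean`, `ctmax_true_sd`), truncated below at the
#' starting temperature, and derives the LOE time from the heating ramp.
#'
#' @param truth a [sim_fish_truth].
#' @param start_temp_c ramp starting temperature, deg C (must be below
#'   `ctmax_true_mean`).
#' @param ramp_rate_c_per_min heating rate, deg C per minute (> 0).
#' @param seed RNG seed.
#' @param log_interval_s sampling interval of the ramp log, seconds.
#' @return An object of class `ctmax_record`: a list with `fish_id`,
#'   `loe_temp_c`, `loe_time_min`, `start_temp_c`, `ramp_rate_c_per_min`
#'   and a `ramp_log` data frame (`time_min`, `temp_c`).
#' @export
simulate_ctmax <- function(truth, start_temp_c = 18,
                           ramp_rate_c_per_min = 0.3, seed = NULL,
                           log_interval_s = 30) {
  if (ramp_rate_c_per_min <= 0) stop("ramp_rate must be > 0", call. = FALSE)
  if (start_temp_c >= truth$ctmax_true_mean) {
    stop("start_temp_c must be below ctmax_true_mean", call. = FALSE)
  }
  loe <- if (truth$ctmax_true_sd == 0) {
    truth$ctmax_true_mean
  } else {
    with_seed(seed, {
      x <- stats::rnorm(1, truth$ctmax_true_mean, truth$ctmax_true_sd)
      while (x <= start_temp_c) {
        x <- stats::rnorm(1, truth$ctmax_true_mean, truth$ctmax_true_sd)
      }
      x
    })
  }
  loe_time <- (loe - start_temp_c) / ramp_rate_c_per_min
  log_t <- seq(0, ceiling(loe_time) + 1, by = log_interval_s / 60)
  ramp_log <- data.frame(time_min = log_t,
                         temp_c = start_temp_c + ramp_rate_c_per_min * log_t)
  structure(list(fish_id = truth$fish_id, loe_temp_c = loe,
                 loe_time_min = loe_time, start_temp_c = start_temp_c,
                 ramp_rate_c_per_min = ramp_rate_c_per_min,
                 ramp_log = ramp_log),
            class = "ctmax_record")
}

# Built-in per-watershed generative parameters. SMR at the site's ambient
# mean, Q10 sensitivity, EPOC excess and decay, and the CT-max
# distribution; diurnal half-range amplitudes span the 2.4-3.9 deg C daily
# ranges observed across the four streams.
watershed_truth_defaults <- function() {
  data.frame(
    watershed = c("Alsea", "Siletz", "McKenzie", "N. Santiam"),
    smr_ref = c(1.6, 1.5, 1.2, 0.9),
    q10_true = c(3.25, 2.02, 1.17, 2.01),
    epoc_magnitude = c(11.2, 7.5, 5.4, 9.9),
    epoc_rate_k = c(0.07, 0.08, 0.06, 0.05),
    ctmax_mean = c(29.775, 30.375, 27.25, 27.29),
    ctmax_sd = c(0.30, 0.17, 2.00, 0.50),
    diurnal_amplitude_c = c(1.6, 1.2, 1.4, 1.95),
    smr_cv = 0.10, epoc_cv = 0.15, k_cv = 0.10,
    stringsAsFactors = FALSE)
}

#' Default simulation scenario
#'
#' Builds the scenario object consumed by [simulate_cohort()]: the four
#' study watersheds with their site context (stream temperature metrics and
#' treatment temperatures from the packaged site table) and per-watershed
#' generative truth distributions.
#'
#' @param watersheds character vector of watershed names to include.
#' @param n_per_treatment fish per temperature treatment (default 8).
#' @param treatments subset of `c("Ambient", "Max", "Climate")`.
#' @param design a [trial_design] used as the template for every trial.
#' @return A list of class `sim_scenario`.
#' @export
default_scenario <- function(watersheds = c("Alsea", "Siletz", "McKenzie",
                                            "N. Santiam"),
                             n_per_treatment = 8,
                             treatments = c("Ambient", "Max", "Climate"),
                             design = trial_design()) {
  ctx <- site_context()
  tru <- watershed_truth_defaults()
  missing <- setdiff(watersheds, ctx$watershed)
  if (length(missing) > 0) {
    stop("unknown watershed(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(watersheds = watersheds,
                 context = ctx[ctx$watershed %in% watersheds, , drop = FALSE],
                 truth = tru[tru$watershed %in% watersheds, , drop = FALSE],
                 n_per_treatment = n_per_treatment,
                 treatments = treatments,
                 design = design),
            class = "sim_scenario")
}

#' Simulate a full study cohort
#'
#' Generates the complete study dataset: `n_per_treatment` fish per
#' temperature treatment per watershed (8 x 3 x 4 = 96 under the default
#' scenario), each with morphometrics drawn so Fulton's condition factor
#' centres near 1.00, one respirometry trial trace (Ambient fish get the
#' diurnal temperature profile; Max and Climate fish constant profiles),
#' and - for Ambient fish only - one CT-max trial. Per-watershed
#' empty-chamber traces are generated for background correction. All
#' randomness derives deterministically from `seed` and the fish id.
#'
#' @param scenario a scenario from [default_scenario()].
#' @param seed root RNG seed.
#' @param traces if `FALSE`, skip trace simulation and return metadata,
#'   truth and CT-max records only (fast).
#' @return A list of class `sim_cohort` with elements `metadata` (one row
#'   per fish), `truth` (ground-truth table), `traces` (named list of
#'   [o2_trace], if requested), `ctmax` (list of `ctmax_record`),
#'   `backgrounds` (per-watershed list with `model`, `true_slope`,
#'   `fraction`) and `scenario`.
#' @export
simulate_cohort <- function(scenario = default_scenario(), seed = 1,
                            traces = TRUE) {
  if (any(!scenario$treatments %in% c("Ambient", "Max", "Climate"))) {
    stop("treatments must be among Ambient, Max, Climate", call. = FALSE)
  }
  meta <- list(); tru_rows <- list(); trace_list <- list()
  ctmax_list <- list(); backgrounds <- list()
  abbrev <- function(w) toupper(substr(gsub("[^A-Za-z]", "", w), 1, 3))

  for (w in scenario$watersheds) {
    ctx <- scenario$context[scenario$context$watershed == w, ]
    tru <- scenario$truth[scenario$truth$watershed == w, ]
    if (any(is.na(c(ctx$max_treatment_c, ctx$climate_treatment_c,
                    ctx$ambient_mean_c)))) {
      stop("missing treatment temperatures for ", w, call. = FALSE)
    }
    # watershed background: a fixed fraction of the typical fish slope
    ws_seed <- derive_seed(seed, paste0(w, "/bg"))
    frac <- with_seed(ws_seed, stats::runif(1, 0.0015, 0.021))
    typical_slope <- tru$smr_ref * 0.0228 /
      (scenario$design$chamber_volume_l - 0.0228)
    bg_slope <- frac * typical_slope
    bgm <- NULL
    if (traces) {
      pre <- simulate_background_trace(bg_slope, scenario$design,
                                       temp_c = ctx$ambient_mean_c,
                                       seed = ws_seed + 1)
      post <- simulate_background_trace(bg_slope, scenario$design,
                                        temp_c = ctx$ambient_mean_c,
                                        seed = ws_seed + 2)
      bgm <- fit_background(pre, post,
                            cycle_plan(scenario$design$measure_min,
                                       scenario$design$flush_min))
    }
    backgrounds[[w]] <- list(model = bgm, true_slope = bg_slope,
                             fraction = frac)

    fish_n <- 0
    for (tr in scenario$treatments) {
      temp_target <- switch(tr,
                            Ambient = ctx$ambient_mean_c,
                            Max = ctx$max_treatment_c,
                            Climate = ctx$climate_treatment_c)
      for (i in seq_len(scenario$n_per_treatment)) {
        fish_n <- fish_n + 1
        fid <- sprintf("%s_%s%02d", abbrev(w), substr(tr, 1, 1), i)
        fs <- derive_seed(seed, fid)
        draws <- with_seed(fs, list(
          fl = min(max(stats::rnorm(1, 130, 12), 100), 181),
          k = min(max(stats::rnorm(1, 1.00, 0.04), 0.90), 1.16),
          smr_mult = exp(stats::rnorm(1, 0, tru$smr_cv)),
          epoc_mult = exp(stats::rnorm(1, 0, tru$epoc_cv)),
          k_mult = exp(stats::rnorm(1, 0, tru$k_cv)),
          dur = sample(18:24, 1)))
        mass_g <- draws$k * draws$fl^3 / 1e5
        truth <- sim_fish_truth(
          fish_id = fid, mass_g = mass_g, fork_length_mm = draws$fl,
          smr_ref = tru$smr_ref * draws$smr_mult, t_ref_c = ctx$ambient_mean_c,
          q10_true = tru$q10_true,
          epoc_magnitude = tru$epoc_magnitude * draws$epoc_mult,
          epoc_rate_k = tru$epoc_rate_k * draws$k_mult,
          ctmax_true_mean = tru$ctmax_mean, ctmax_true_sd = tru$ctmax_sd)

        design <- scenario$design
        design$duration_h <- draws$dur
        design$seed <- fs + 1
        design$background_slope <- bg_slope
        profile <- if (tr == "Ambient") {
          diurnal_profile(ctx$ambient_mean_c, tru$diurnal_amplitude_c,
                          start_hour = design$start_hour)
        } else {
          constant_profile(temp_target)
        }

        if (traces) {
          sim <- simulate_trial(truth, design, profile)
          trace_list[[fid]] <- sim$trace
        }
        if (tr == "Ambient") {
          ctmax_list[[fid]] <- simulate_ctmax(
            truth, start_temp_c = min(ctx$ambient_mean_c, 18),
            seed = fs + 2)
        }
        meta[[fid]] <- data.frame(
          fish_id = fid, watershed = w, treatment = tr,
          mass_g = mass_g, fork_length_mm = draws$fl,
          condition_k = condition_factor(mass_g, draws$fl),
          duration_h = draws$dur, treatment_temp_c = temp_target,
          stringsAsFactors = FALSE)
        tru_rows[[fid]] <- data.frame(
          fish_id = fid, watershed = w, treatment = tr,
          smr_ref = truth$smr_ref, t_ref_c = truth$t_ref_c,
          q10_true = truth$q10_true, epoc_magnitude = truth$epoc_magnitude,
          epoc_rate_k = truth$epoc_rate_k,
          ctmax_true_mean = truth$ctmax_true_mean,
          ctmax_true_sd = truth$ctmax_true_sd,
          background_slope = bg_slope, background_fraction = frac,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(metadata = do.call(rbind, unname(meta)),
                 truth = do.call(rbind, unname(tru_rows)),
                 traces = if (traces) trace_list else NULL,
                 ctmax = ctmax_list,
                 backgrounds = backgrounds,
                 scenario = scenario,
                 seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d fish | %d watershed(s) | seed %s | traces: %s\n",
              nrow(x$metadata), length(unique(x$metadata$watershed)),
              x$seed, !is.null(x$traces)))
  invisible(x)
}
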