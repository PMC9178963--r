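# Shared in-code fixtures: small MO2 series and fast trial designs.

# Minimal mo2_series-shaped data frame (10-min cycles, mid-times at 5 min
# offsets) for trait and recovery functions.
make_series <- function(mo2, temp_c = 18, cycle_min = 10,
                        fish_id = "TEST", mass_kg = 0.0228,
                        chamber_volume_l = 2) {
  n <- length(mo2)
  temp_c <- rep_len(temp_c, n)
  out <- data.frame(cycle_index = seq_len(n),
                    mid_time_s = (seq_len(n) - 0.5) * cycle_min * 60,
                    mo2 = mo2, mean_temp_c = temp_c,
                    r_squared = 1, flagged_negative = mo2 < 0)
  attr(out, "fish_id") <- fish_id
  attr(out, "mass_kg") <- mass_kg
  attr(out, "chamber_volume_l") <- chamber_volume_l
  class(out) <- c("mo2_series", "data.frame")
  out
}

# Fast noiseless design: coarse probe sampling keeps trials cheap while
# leaving cycle structure and slope recovery intact.
fast_design <- function(duration_h = 2, noise_sd = 0, dt = 5, ...) {
  trial_design(duration_h = duration_h, sample_interval_s = dt,
               noise_sd = noise_sd, ...)
}

default_truth <- function(fish_id = "F1", ...) {
  args <- list(fish_id = fish_id, mass_g = 22.8, fork_length_mm = 130.2,
               smr_ref = 2, t_ref_c = 18, q10_true = 2,
               epoc_magnitude = 8, epoc_rate_k = 0.1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_fish_truth, args)
}
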