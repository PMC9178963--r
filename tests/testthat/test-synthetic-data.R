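test_that("a 24-h trial contains 144 measurement phases", {
  sim <- simulate_trial(default_truth(), fast_design(duration_h = 24),
                        constant_profile(18))
  runs <- rle(sim$trace$phase)
  expect_equal(sum(runs$values == "measure"), 144)
  expect_equal(nrow(segment_cycles(sim$trace, cycle_plan())), 144)
})

test_that("noiseless steady-state measurement phases decline exactly linearly", {
  tr <- default_truth(epoc_magnitude = 0)
  sim <- simulate_trial(tr, fast_design(duration_h = 1, dt = 1),
                        constant_profile(18))
  x <- sim$trace
  for (ci in 0:5) {
    idx <- x$time_s >= ci * 600 & x$time_s < ci * 600 + 360
    d <- diff(x$o2_mg_per_l[idx])
    expect_true(all(abs(d - d[1]) < 1e-12))
  }
})

test_that("Q10 temperature scaling drives the generated steady rate", {
  # smr_ref 2.0 at 18 degC with Q10 = 2 gives 4.0 at 28 degC
  tr <- default_truth(epoc_magnitude = 0)
  sim <- simulate_trial(tr, fast_design(duration_h = 2, dt = 1,
                                        background_fraction = 0),
                        constant_profile(28))
  ser <- build_mo2_series(sim$trace, cycle_plan(), background_model(0, 0),
                          mass_kg = 0.0228)
  expect_true(all(abs(ser$mo2 - 4.0) < 1e-6))
  expect_equal(true_mo2(tr, 100, 28), 2 * 2^((28 - 18) / 10))
})

test_that("trial simulation rejects malformed designs and short profiles", {
  expect_error(trial_design(duration_h = 24.05),
               "whole number of .*cycles")
  short_profile <- data.frame(time_s = c(0, 3600), temp_c = c(18, 18))
  expect_error(simulate_trial(default_truth(), fast_design(duration_h = 2),
                              short_profile),
               "shorter than trial")
})

test_that("identical seeds reproduce traces byte-for-byte", {
  d <- fast_design(duration_h = 1, noise_sd = 0.02, seed = 99)
  a <- simulate_trial(default_truth(), d, constant_profile(18))
  b <- simulate_trial(default_truth(), d, constant_profile(18))
  expect_identical(a$trace$o2_mg_per_l, b$trace$o2_mg_per_l)
  d2 <- fast_design(duration_h = 1, noise_sd = 0.02, seed = 100)
  c2 <- simulate_trial(default_truth(), d2, constant_profile(18))
  expect_false(identical(a$trace$o2_mg_per_l, c2$trace$o2_mg_per_l))
})

test_that("CT-max draws respect the ramp and degenerate sd", {
  tr <- default_truth(ctmax_true_mean = 30, ctmax_true_sd = 0)
  rec <- simulate_ctmax(tr, start_temp_c = 18, ramp_rate_c_per_min = 0.3)
  expect_equal(rec$loe_temp_c, 30)
  expect_equal(rec$loe_time_min, 40)

  tr2 <- default_truth(ctmax_true_mean = 30, ctmax_true_sd = 0.5)
  a <- simulate_ctmax(tr2, seed = 3)
  b <- simulate_ctmax(tr2, seed = 3)
  expect_identical(a$loe_temp_c, b$loe_temp_c)
  expect_gt(a$loe_temp_c, 18)
  expect_error(simulate_ctmax(tr, ramp_rate_c_per_min = 0),
               "ramp_rate")
})

test_that("cohort structure matches the study design", {
  full <- simulate_cohort(default_scenario(), seed = 2, traces = FALSE)
  expect_equal(nrow(full$metadata), 96)
  expect_equal(as.vector(table(full$metadata$watershed)), rep(24L, 4))
  expect_equal(sum(full$metadata$treatment == "Ambient"), 32)
  expect_equal(length(full$ctmax), 32)  # Ambient fish only

  small <- simulate_cohort(default_scenario(watersheds = "Siletz",
                                            treatments = "Ambient"),
                           seed = 2, traces = FALSE)
  expect_equal(nrow(small$metadata), 8)
})

test_that("generated condition factors centre near 1 within the observed band", {
  coh <- simulate_cohort(default_scenario(), seed = 4, traces = FALSE)
  k <- coh$metadata$condition_k
  expect_gte(mean(k >= 0.93 & k <= 1.13), 0.95)
  expect_equal(mean(k), 1.0, tolerance = 0.02)
  expect_equal(k, condition_factor(coh$metadata$mass_g,
                                   coh$metadata$fork_length_mm))
})

test_that("cohort generation is deterministic in the root seed", {
  a <- simulate_cohort(default_scenario(watersheds = "Alsea",
                                        treatments = "Max",
                                        design = fast_design(duration_h = 1)),
                       seed = 5)
  b <- simulate_cohort(default_scenario(watersheds = "Alsea",
                                        treatments = "Max",
                                        design = fast_design(duration_h = 1)),
                       seed = 5)
  expect_identical(a$metadata, b$metadata)
  fid <- names(a$traces)[1]
  expect_identical(a$traces[[fid]]$o2_mg_per_l, b$traces[[fid]]$o2_mg_per_l)
})

test_that("simulated background stays within the configured fraction band", {
  coh <- simulate_cohort(default_scenario(watersheds = c("Alsea", "Siletz")),
                         seed = 6, traces = FALSE)
  fr <- coh$truth$background_fraction
  expect_true(all(fr >= 0.0015 & fr <= 0.021))
  # trial-level realised fraction agrees with the requested one
  tr <- default_truth(epoc_magnitude = 0)
  sim <- simulate_trial(tr, fast_design(background_fraction = 0.01),
                        constant_profile(18))
  expect_equal(sim$truth$background_fraction_realised, 0.01,
               tolerance = 1e-9)
})

test_that("full downstream pipeline recovers truth from noiseless trials", {
  # SMR within 1% and Q10 within 2% across two constant-temperature trials
  tr <- default_truth(epoc_magnitude = 8, epoc_rate_k = 0.1)
  d <- fast_design(duration_h = 6, dt = 1)
  temps <- c(14, 19)
  rmrs <- numeric(2)
  for (i in 1:2) {
    sim <- simulate_trial(tr, d, constant_profile(temps[i]))
    bg <- background_model(sim$truth$background_slope,
                           sim$truth$background_slope)
    ser <- build_mo2_series(sim$trace, cycle_plan(), bg, mass_kg = 0.0228)
    s <- estimate_smr(ser)
    truth_smr <- 2 * 2^((temps[i] - 18) / 10)
    expect_equal(s$smr, truth_smr, tolerance = 0.01)
    m <- estimate_mmr(ser)
    rec <- recovery_metrics(ser, s$smr, m$mmr, m$mmr_time_s)
    rmr <- estimate_rmr(ser, m$mmr_time_s + rec$time_epoc_h * 3600)
    rmrs[i] <- mean(rmr$rmr)
  }
  q <- q10(rmrs[1], rmrs[2], temps[1], temps[2])
  expect_equal(q$q10, 2, tolerance = 0.02)
})

test_that("EPOC end detection matches the analytic crossing within one cycle", {
  tr <- default_truth()  # smr 2, epoc 8, k = 0.1/min at constant 18 degC
  sim <- simulate_trial(tr, fast_design(duration_h = 3, dt = 1),
                        constant_profile(18))
  ser <- build_mo2_series(sim$trace, cycle_plan(),
                          background_model(sim$truth$background_slope,
                                           sim$truth$background_slope),
                          mass_kg = 0.0228)
  s <- estimate_smr(ser); m <- estimate_mmr(ser)
  rec <- recovery_metrics(ser, s$smr, m$mmr, m$mmr_time_s)
  analytic_min <- log(8 / (0.2 * 2)) / 0.1  # 1.2*SMR crossing of the true curve
  detected_min <- rec$time_epoc_h * 60 + m$mmr_time_s / 60
  expect_lt(abs(detected_min - analytic_min), 10)
})
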