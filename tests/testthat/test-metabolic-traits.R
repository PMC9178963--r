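test_that("SMR is the mean of the lowest 20% of MO2 values", {
  ser <- make_series(rep(2, 100))
  s <- estimate_smr(ser)
  expect_equal(s$smr, 2)
  expect_equal(s$smr_n, 20)

  ser2 <- make_series(1:100)
  expect_equal(estimate_smr(ser2)$smr, mean(1:20))
  expect_equal(estimate_smr(ser2)$smr, 10.5)

  expect_equal(estimate_smr(make_series(rnorm(120, 5)))$smr_n, 24)
  expect_error(estimate_smr(make_series(1:4)), "at least 5")

  # the temperatures of the selected cycles are averaged
  ser3 <- make_series(c(5, 4, 3, 2, 1, 6, 7, 8, 9, 10),
                      temp_c = c(20, 20, 20, 17, 16, 21, 21, 21, 21, 21))
  s3 <- estimate_smr(ser3)
  expect_equal(s3$smr_n, 2)
  expect_equal(s3$smr, 1.5)
  expect_equal(s3$smr_temp_c, 16.5)
})

test_that("MMR is the per-cycle maximum and sets the recovery clock", {
  ser <- make_series(c(3, 9, 5))
  m <- estimate_mmr(ser)
  expect_equal(m$mmr, 9)
  expect_equal(m$mmr_cycle, 2)

  # monotone-decaying recovery: MMR is the first entry
  dec <- make_series(10 * exp(-0.1 * (1:20)))
  expect_equal(estimate_mmr(dec)$mmr_cycle, 1)

  # window-averaged truth for the first cycle of a simulated trial
  tr <- default_truth()  # smr 2, epoc 8, k 0.1
  sim <- simulate_trial(tr, fast_design(duration_h = 2, dt = 1,
                                        background_fraction = 0),
                        constant_profile(18))
  ser2 <- build_mo2_series(sim$trace, cycle_plan(), background_model(0, 0),
                           mass_kg = 0.0228)
  m2 <- estimate_mmr(ser2)
  w <- 6  # minutes of measurement phase
  expected <- 2 + 8 * (1 - exp(-0.1 * w)) / (0.1 * w)
  expect_equal(m2$mmr, expected, tolerance = 0.02)
  expect_equal(m2$mmr_cycle, 1)
})

test_that("aerobic scope arithmetic and the printed FAS decline", {
  sc <- aerobic_scope(2, 10)
  expect_equal(sc$aas, 8)
  expect_equal(sc$fas, 5)
  eq <- aerobic_scope(3, 3)
  expect_equal(eq$aas, 0)
  expect_equal(eq$fas, 1)
  expect_error(aerobic_scope(0, 10), "smr")

  # group mean FAS falling from 12.025 (Ambient) to 6.224 (Climate)
  decline_pct <- 100 * (12.025 - 6.224) / 12.025
  expect_equal(round(decline_pct), 48)
})

test_that("AAS and FAS are mutually consistent", {
  set.seed(11)
  for (i in 1:50) {
    smr <- runif(1, 0.5, 3)
    mmr <- smr + runif(1, 0, 10)
    sc <- aerobic_scope(smr, mmr)
    expect_equal(sc$aas, smr * (sc$fas - 1), tolerance = 1e-12)
  }
})

test_that("RMR bins post-EPOC values by temperature and enforces n >= 3", {
  ser <- make_series(rep(1.5, 40), temp_c = rep(18 + c(-0.4, 0, 0.2, 0.4), 10))
  r <- estimate_rmr(ser, epoc_end_s = 0)
  expect_equal(nrow(r), 1)
  expect_equal(r$temp_bin_c, 18)
  expect_equal(r$rmr, 1.5)
  expect_equal(r$n, 40L)

  # a bin with only 2 measurements is dropped
  ser2 <- make_series(c(1, 1, 1, 2, 2), temp_c = c(18, 18, 18, 21, 21))
  r2 <- estimate_rmr(ser2, epoc_end_s = 0)
  expect_equal(r2$temp_bin_c, 18)
  expect_false(21 %in% r2$temp_bin_c)

  expect_warning(out <- estimate_rmr(ser, epoc_end_s = 1e9), "no post-EPOC")
  expect_equal(nrow(out), 0)
})

test_that("a noiseless diurnal trial yields few distinct RMR temperatures", {
  tr <- default_truth(epoc_magnitude = 0)
  d <- fast_design(duration_h = 24)
  sim <- simulate_trial(tr, d,
                        diurnal_profile(18.3, 1.7, start_hour = d$start_hour))
  ser <- build_mo2_series(sim$trace, cycle_plan(),
                          background_model(sim$truth$background_slope,
                                           sim$truth$background_slope),
                          mass_kg = 0.0228)
  r <- estimate_rmr(ser, epoc_end_s = 0)
  expect_lte(nrow(r), 4)  # 16.6-20.0 degC span covers at most 4 integer bins
  expect_gte(nrow(r), 2)
})

test_that("Q10 follows its closed form and composes across segments", {
  expect_equal(q10(1, 2, 10, 20)$q10, 2)
  expect_equal(q10(1.5, 1.5, 10, 20)$q10, 1)  # temperature independence
  expect_equal(q10(1.0, 1.5, 17, 22)$q10, 1.5^2)
  expect_equal(q10(1.0, 1.5, 17, 22)$q10, 2.25)
  expect_error(q10(0, 1, 10, 20), "rates")
  expect_error(q10(1, 1, 15, 15), "differ")

  # rates generated from one true Q10 chain consistently over [T1, T3]
  true_q <- 2.4
  r <- function(t) 1.1 * true_q^((t - 10) / 10)
  expect_equal(q10(r(10), r(16), 10, 16)$q10, true_q, tolerance = 1e-12)
  expect_equal(q10(r(10), r(23), 10, 23)$q10, true_q, tolerance = 1e-12)
})

test_that("Fulton's condition factor", {
  expect_equal(condition_factor(10, 100), 1.0)
  expect_equal(condition_factor(22.8, 130.2), 1.033, tolerance = 1e-3)
  expect_error(condition_factor(-1, 100), "> 0")
})

test_that("mass-scaling check flags isometry and recovers exponents", {
  mass <- exp(seq(log(0.015), log(0.035), length.out = 12))
  rate <- 2 * mass  # whole-animal rate exactly proportional to mass
  chk <- suppressWarnings(mass_scaling_check(rate, mass))  # exact-fit lm note
  expect_equal(chk$slope, 1, tolerance = 1e-10)
  expect_false(chk$mass_correction_needed)

  expect_error(mass_scaling_check(c(1, 2), c(0.02, 0.03)), "3 fish")

  # Monte Carlo: exponent 0.85 with lognormal noise, n = 24
  set.seed(21)
  hits <- 0
  for (i in 1:200) {
    m <- exp(rnorm(24, log(0.0228), 0.2))
    rt <- exp(0.85 * log(m) + log(80) + rnorm(24, 0, 0.05))
    est <- mass_scaling_check(rt, m)$slope
    if (abs(est - 0.85) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
})

test_that("trait ordering SMR <= RMR <= MMR holds on noiseless data", {
  tr <- default_truth()
  sim <- simulate_trial(tr, fast_design(duration_h = 4, dt = 1),
                        constant_profile(18))
  ser <- build_mo2_series(sim$trace, cycle_plan(),
                          background_model(sim$truth$background_slope,
                                           sim$truth$background_slope),
                          mass_kg = 0.0228)
  t <- derive_traits(ser, 22.8, 130.2)
  rec <- recovery_metrics(ser, t$smr, t$mmr, t$mmr_time_s)
  rmr <- estimate_rmr(ser, t$mmr_time_s + rec$time_epoc_h * 3600)
  expect_true(all(t$smr <= rmr$rmr + 1e-9))
  expect_true(all(rmr$rmr <= t$mmr + 1e-9))
  expect_gte(t$fas, 1)
  expect_gte(t$aas, 0)
})
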