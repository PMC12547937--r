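test_that("landmarks are zero on a flat trace and exact on a staircase", {
  ld0 <- landmark_deltas(flat_recording())
  expect_equal(ld0$delta_pulse6, 0)
  expect_equal(ld0$delta_pulse10, 0)
  expect_equal(ld0$delta_total, 0)

  # +2 fF after each of the 6 short pulses, nothing else
  ld <- landmark_deltas(staircase_recording(step_fF = 2, n_steps = 6))
  expect_lt(abs(ld$delta_pulse6 - 12), 1e-9)
  expect_lt(abs(ld$delta_pulse10 - 12), 1e-9)
  expect_lt(abs(ld$delta_total - 12), 1e-9)
})

test_that("landmark windows fail loudly when empty or mismatched", {
  rec <- staircase_recording()
  # drop the samples after pulse 6 to force an empty landmark window
  p <- rec$pulses
  a <- p$start[6] + p$duration[6]
  keep <- !(rec$time_ms >= a & rec$time_ms < a + 300)
  rec2 <- capacitance_recording("fix", rec$time_ms[keep],
                                rec$cm_fF[keep], p, rec$cm0_pF)
  expect_error(landmark_deltas(rec2), "pulse 6")
  expect_error(landmark_deltas(rec, pulse_protocol("potentiation15")),
               "15")
})

test_that("pool decomposition handles both RRP conventions", {
  pe <- pool_decomposition(c(12, 12, 12), cm0 = 12)
  expect_equal(pe$irp_fF, 12)
  expect_equal(pe$irp_fF_per_pF, 1.0)
  expect_equal(pe$rrp_fF, 0)             # incremental default

  pe2 <- pool_decomposition(c(3.5, 94.5, 240), cm0 = 10.8)
  expect_equal(pe2$rrp_fF, 91)
  expect_equal(pe2$total_fF_per_pF, 240 / 10.8)

  cum <- pool_decomposition(c(3.5, 94.5, 240), cm0 = 10.8,
                            convention = "cumulative")
  expect_equal(cum$rrp_fF - pe2$rrp_fF, pe2$irp_fF)
})

test_that("pools are ordered on monotone traces", {
  for (seed in 1:5) {
    cfg <- pool_sim_config(runif(1, 2, 15), runif(1, 40, 120),
                           sustained_rate = runif(1, 0, 20),
                           release_fraction_short = runif(1, 0.2, 0.5),
                           release_fraction_long = runif(1, 0.3, 0.7),
                           noise_sd = 0, seed = seed)
    ld <- landmark_deltas(simulate_capacitance(cfg)$recording)
    expect_lte(0, ld$delta_pulse6)
    expect_lte(ld$delta_pulse6, ld$delta_pulse10 + 1e-9)
    expect_lte(ld$delta_pulse10, ld$delta_total + 1e-9)
  }
})

test_that("QC taxonomy classifies the three canonical fixtures", {
  expect_equal(qc_classify(flat_recording(peak_pA = -250)),
               "no_exocytosis")
  expect_equal(qc_classify(staircase_recording(step_fF = 2, n_steps = 10)),
               "provoked")
  expect_equal(qc_classify(random_walk_recording(step_sd = 4, seed = 11)),
               "spontaneous")
  expect_equal(qc_classify(flat_recording(), unstable = TRUE), "unstable")
})

test_that("QC requires per-pulse current annotations", {
  rec <- flat_recording()
  rec$pulses$peak_pA <- NA_real_
  expect_error(qc_classify(rec), "peak currents")
})

test_that("potentiation delta is exact on flat and staircase fixtures", {
  pr <- pulse_protocol("potentiation15")
  expect_equal(potentiation_delta(flat_recording(protocol = pr),
                                  protocol = pr)$delta_fF, 0)
  rec <- staircase_recording(step_fF = 10, n_steps = 15, cm0 = 10,
                             protocol = pr)
  d <- potentiation_delta(rec, protocol = pr)
  expect_lt(abs(d$delta_fF - 150), 1e-9)
  expect_equal(d$delta_fF_per_pF, d$delta_fF / 10)
})

test_that("a condition multiplier on the train scales the delta exactly", {
  pr <- pulse_protocol("potentiation15")
  ctrl <- staircase_recording(step_fF = 121 / 15, n_steps = 15,
                              protocol = pr)
  boosted <- staircase_recording(step_fF = 2.75 * 121 / 15, n_steps = 15,
                                 protocol = pr)
  d0 <- potentiation_delta(ctrl, pr)$delta_fF
  d1 <- potentiation_delta(boosted, pr)$delta_fF
  expect_equal(d0, 121, tolerance = 1e-9)
  expect_equal(d1 / d0, 2.75, tolerance = 1e-9)
})

test_that("spike count and waveform metrics are recovered from construction", {
  vt <- simulate_voltage_trace(c(100, 300, 500, 700, 900), 1100,
                               threshold = -20, peak = 30,
                               rise_slope = 12.5, half_width = 19.1,
                               sample_interval_ms = 0.1)
  aps <- detect_spikes(vt)
  expect_equal(aps$n_spikes, 5)
  expect_equal(mean(aps$half_width_ms), 19.1, tolerance = 0.1 / 19.1)
  expect_equal(mean(aps$overshoot_mV), 30, tolerance = 1e-6)
  expect_lt(abs(mean(aps$threshold_mV) - (-20)), 1)
  expect_equal(aps$resting_mV, -70)
})

test_that("subthreshold depolarizations yield zero spikes", {
  t <- seq(0, 500, 0.5)
  v <- -70 + 30 * (t > 100 & t < 400)     # peaks at -40, below -20
  vt <- voltage_trace("c", t, v,
                      data.frame(start = 100, end = 400, current_pA = 10))
  expect_equal(detect_spikes(vt)$n_spikes, 0)
})

test_that("spike detection is robust to 2 mV noise with a lockout", {
  vt <- simulate_voltage_trace(c(100, 400, 700), 1000,
                               threshold = -20, peak = 30,
                               rise_slope = 12.5, half_width = 19.1,
                               noise_sd = 2, sample_interval_ms = 0.5,
                               seed = 21)
  aps <- detect_spikes(vt, refractory_ms = 60)
  expect_equal(aps$n_spikes, 3)
})

test_that("spikes outside the annotated step are not counted", {
  vt <- simulate_voltage_trace(c(100, 600), 1000,
                               threshold = -20, peak = 30,
                               rise_slope = 12.5, half_width = 19.1,
                               step = data.frame(start = 0, end = 500,
                                                 current_pA = 30))
  expect_equal(detect_spikes(vt)$n_spikes, 1)
})

test_that("noisy pool estimates recover the model truth within the bound", {
  # 100 seeded draws at noise_sd = 5 fF; windows hold 30 samples, so the
  # acceptance bound on the median absolute landmark error is
  # 2 * 5 / sqrt(30) fF
  errs_irp <- errs_rrp <- numeric(100)
  for (i in 1:100) {
    set.seed(1000 + i)
    fs <- runif(1, 0.2, 0.5); fl <- runif(1, 0.3, 0.7)
    irp <- runif(1, 2, 20); rrp <- runif(1, 40, 150)
    cfg <- pool_sim_config(irp, rrp, release_fraction_short = fs,
                           release_fraction_long = fl, noise_sd = 5,
                           seed = 2000 + i)
    ld <- landmark_deltas(simulate_capacitance(cfg)$recording)
    true6 <- oracle_cumulative_release(irp, rrp, fs, fl, 6, 0)
    true10 <- oracle_cumulative_release(irp, rrp, fs, fl, 6, 4)
    errs_irp[i] <- ld$delta_pulse6 - true6
    errs_rrp[i] <- (ld$delta_pulse10 - ld$delta_pulse6) - (true10 - true6)
  }
  bound <- 2 * 5 / sqrt(30)
  expect_lt(median(abs(errs_irp)), bound)
  expect_lt(median(abs(errs_rrp)), bound)
})
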