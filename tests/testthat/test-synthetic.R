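test_that("generators are bit-reproducible given the seed", {
  cfg <- simulation_config(seed = 17)
  p1 <- simulate_pad_counts(cfg); p2 <- simulate_pad_counts(cfg)
  expect_identical(p1[["290"]][[3]]$counts, p2[["290"]][[3]]$counts)
  m <- synthetic_channel_model(5, 2)
  expect_identical(simulate_intensity_measurements(m, c(0, 5, 10), seed = 4),
                   simulate_intensity_measurements(m, c(0, 5, 10), seed = 4))
  expect_identical(simulate_bleach_trace(10, -0.01, max_dose = 100, seed = 9),
                   simulate_bleach_trace(10, -0.01, max_dose = 100, seed = 9))
  s1 <- simulate_multicolor(c(0.85, 0.87), seed = 2)
  s2 <- simulate_multicolor(c(0.85, 0.87), seed = 2)
  expect_identical(s1$pairs, s2$pairs)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(doses = c(10, 20, 40, 80, 160, 320)),
               "include 0")
  expect_error(simulation_config(capacity = 5, n0 = 8), "exceed")
  expect_error(simulation_config(doses = c(0, -5, 10, 20, 40, 80)),
               "non-negative")
})

test_that("noiseless control pads grow exactly exponentially", {
  cfg <- simulation_config(seed = 1, noise_sd = 0, n_pads = 1)
  pads <- simulate_pad_counts(cfg)
  ctrl <- pads[["0"]][[1]]
  gr <- growth_rate_endpoint(ctrl)$growth_rate_per_h
  # rounding to integer counts leaves < 1% on the endpoint estimate
  expect_equal(gr, cfg$gr0, tolerance = 0.01)
  # a dose 20x the ED50 yields a near-flat trajectory
  cfg_hi <- simulation_config(seed = 1, noise_sd = 0, n_pads = 1,
                              doses = c(0, 5800))
  high <- simulate_pad_counts(cfg_hi)[["5800"]][[1]]
  expect_lt(growth_rate_endpoint(high)$growth_rate_per_h, 0.05 * cfg$gr0)
})

test_that("simulated data satisfy downstream type invariants by construction", {
  cfg <- simulation_config(seed = 23)
  pads <- simulate_pad_counts(cfg)
  expect_equal(length(pads), length(cfg$doses))
  for (dd in pads) for (p in dd) {
    expect_s3_class(p, "pad_counts")
    expect_true(all(diff(p$times) > 0))
    expect_true(all(p$counts >= 1))
  }
  m <- simulate_intensity_measurements(synthetic_channel_model(5, 2),
                                       c(0, 5, 10, 20), seed = 3)
  expect_true(all(m$sd_signal >= 0))
  expect_true(all(m$mean_signal >= m$mean_background - 3 * m$sd_signal))
})

test_that("onset delay postpones morbidity without changing the control", {
  cfg_d <- simulation_config(seed = 4, noise_sd = 0, n_pads = 1,
                             onset_delay = 3)
  cfg_0 <- simulation_config(seed = 4, noise_sd = 0, n_pads = 1)
  delayed <- simulate_pad_counts(cfg_d)[["145"]][[1]]
  instant <- simulate_pad_counts(cfg_0)[["145"]][[1]]
  # during the delay the pad grows at the control rate: early residuals stay
  # below one cell (integer rounding is the only deviation)
  r <- early_window_residuals(delayed, window = 180)
  expect_lt(max(abs(r$residual[r$time_min <= 180])), 1)
  # afterwards it falls behind its early trend but stays ahead of the
  # instantaneous-onset pad
  expect_lt(min(r$residual), -1)
  expect_gt(delayed$counts[length(delayed$counts)],
            instant$counts[length(instant$counts)])
  # control unaffected by the delay switch
  expect_identical(simulate_pad_counts(cfg_d)[["0"]][[1]]$counts,
                   simulate_pad_counts(cfg_0)[["0"]][[1]]$counts)
})

test_that("pads exceeding the field-of-view capacity are flagged excluded", {
  cfg <- simulation_config(seed = 2, noise_sd = 0, n_pads = 1, capacity = 100)
  pads <- simulate_pad_counts(cfg)
  expect_true(pads[["0"]][[1]]$excluded)       # control outgrows 100 cells
  expect_false(pads[["580"]][[1]]$excluded)    # arrested colony stays small
})

test_that("simulate -> fit round trip recovers the dose-effect truth", {
  cfg <- simulation_config(seed = 42)
  fit <- fit_dose_response(pads_to_dose_response(simulate_pad_counts(cfg)))
  expect_equal(fit$ed50, cfg$ed50, tolerance = 0.10)
  expect_equal(fit$gr0, 1, tolerance = 0.05)
})

test_that("intensity round trip recovers channel slopes within 5%", {
  m <- synthetic_channel_model(probe_rate = 10, background_rate = 4,
                               camera_floor = 80, cell_cv = 0.12)
  meas <- simulate_intensity_measurements(m, c(0, 5, 10, 20, 40), 500, seed = 8)
  cal <- fit_channel_calibration(meas)
  expect_equal(cal$sig_slope, 14, tolerance = 0.05)
  expect_equal(cal$bg_slope, 4, tolerance = 0.05)
  # dose 0 means are the camera floor
  expect_equal(meas$mean_signal[meas$dose == 0], 80, tolerance = 0.05)
  # probe_rate 0 collapses signal onto background
  dark <- simulate_intensity_measurements(
    synthetic_channel_model(0, 4, camera_floor = 80), c(0, 10, 20), 2000,
    seed = 9)
  expect_equal(dark$mean_signal, dark$mean_background, tolerance = 0.05)
})

test_that("multicolor simulation reproduces the built-in interaction", {
  clean <- simulate_multicolor(c(0.85, 0.87, 0.9), cdi_true = 1,
                               n_reps = 5, noise_sd = 0, seed = 1)
  cdis <- estimate_cdis(clean)
  expect_equal(cdis$cdi, rep(1, 3), tolerance = 1e-12)
  syn <- simulate_multicolor(c(0.85, 0.87), cdi_true = 0.7, n_reps = 20,
                             noise_sd = 0.02, seed = 6)
  expect_equal(mean(estimate_cdis(syn)$cdi), 0.7, tolerance = 0.05 / 0.7)
  single <- simulate_multicolor(0.8, n_reps = 4, noise_sd = 0, seed = 1)
  expect_equal(single$pairs$gr_combined, single$pairs$gr_a)
})

test_that("full pipeline: simulated truth flows through fit and plan", {
  cfg <- simulation_config(seed = 77)
  fit <- fit_dose_response(pads_to_dose_response(simulate_pad_counts(cfg)))
  cal <- toy_cal(1, 0, 0, 0, 0, 1)
  plan <- plan_channels(list(teal = list(cal = cal, ratio = 1, fit = fit)),
                        target_snr = 4, interval_min = 60)
  # the plan's predicted combined fraction must match direct simulation of
  # the planned dose under the generating model, within Monte-Carlo error
  applied <- plan$bands$applied_dose_rate
  truth_frac <- 1 / (1 + (applied / cfg$ed50)^cfg$tau)
  sim_cfg <- simulation_config(seed = 78, doses = c(0, applied, 50, 150,
                                                    300, 600))
  pads <- simulate_pad_counts(sim_cfg)
  gr_ctrl <- aggregate_pads(pads[["0"]])$growth_rate
  gr_at <- aggregate_pads(pads[[as.character(applied)]])$growth_rate
  measured <- normalize_to_control(gr_at, gr_ctrl)
  expect_equal(plan$combined_gr_fraction, truth_frac, tolerance = 0.05)
  expect_equal(measured, truth_frac, tolerance = 0.05)
})
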