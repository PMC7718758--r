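test_that("measured SNR is background-corrected signal over noise", {
  expect_equal(measured_snr(100, 36, 10), 6.4)
  expect_equal(measured_snr(50, 50, 5), 0)
  expect_equal(measured_snr(100, 36, mode = "shot"), 6.4)   # sqrt(100) = 10
  expect_error(measured_snr(10, 5, 0), "positive")
  expect_error(measured_snr(10, 5), "required")
})

test_that("calibration recovers exact linear data to machine precision", {
  doses <- c(0, 5, 10, 20, 40)
  m <- data.frame(dose = doses,
                  mean_signal = 12 * doses + 100,
                  mean_background = 3 * doses + 100,
                  sd_signal = 0.8 * doses + 10,
                  sd_background = 0.3 * doses + 10,
                  n_cells = 500)
  cal <- fit_channel_calibration(m, fluorophore = "exact")
  expect_equal(cal$sig_slope, 12, tolerance = 1e-10)
  expect_equal(cal$sig_intercept, 100, tolerance = 1e-10)
  expect_equal(cal$bg_slope, 3, tolerance = 1e-10)
  expect_equal(cal$sd_slope, 0.8, tolerance = 1e-10)
  expect_equal(cal$sd_intercept, 10, tolerance = 1e-10)
})

test_that("calibration needs 3 distinct doses and flags odd slopes", {
  m <- data.frame(dose = c(5, 5, 5), mean_signal = 1:3,
                  mean_background = 1:3, sd_signal = 1:3)
  expect_error(fit_channel_calibration(m), "3 distinct")
  dim_fp <- data.frame(dose = c(0, 10, 20),
                       mean_signal = c(100, 101, 102),
                       mean_background = c(100, 120, 140),
                       sd_signal = c(5, 6, 7))
  expect_warning(fit_channel_calibration(dim_fp), "not detectable")
})

test_that("calibration slope is within 5% under heteroscedastic noise", {
  model <- synthetic_channel_model(probe_rate = 9, background_rate = 3,
                                   camera_floor = 100, cell_cv = 0.1)
  m <- simulate_intensity_measurements(model, doses = c(0, 5, 10, 20, 40, 80),
                                       n_cells = 500, seed = 21)
  cal <- fit_channel_calibration(m)
  expect_equal(cal$sig_slope, 12, tolerance = 0.05)   # (B+P)*QE
  expect_equal(cal$bg_slope, 3, tolerance = 0.05)
})

test_that("estimated SNR evaluates the fitted lines", {
  # signal-background difference 1.0*LD, noise 0.1*LD + 0.5
  cal <- toy_cal(sig_slope = 1.2, sig_intercept = 50,
                 bg_slope = 0.2, bg_intercept = 50,
                 sd_slope = 0.1, sd_intercept = 0.5)
  expect_equal(estimate_snr(cal, 10 / 3), 4)
  expect_equal(estimate_snr(cal, 0), 0)    # lines cross at dose 0
  # monotone increasing whenever dS*sd_int > dI*sd_slope
  d <- seq(0, 100, by = 0.25)
  expect_true(all(diff(estimate_snr(cal, d)) > 0))
})

test_that("SNR estimated from a calibration fit on noiseless lines matches the generator", {
  doses <- c(0, 4, 8, 16, 32)
  m <- data.frame(dose = doses,
                  mean_signal = 10 * doses + 100,
                  mean_background = 2 * doses + 100,
                  sd_signal = 0.5 * doses + 8)
  cal <- suppressWarnings(fit_channel_calibration(m))
  at <- c(1, 7, 19)
  expect_equal(estimate_snr(cal, at),
               (10 * at + 100 - (2 * at + 100)) / (0.5 * at + 8),
               tolerance = 1e-9)
})

test_that("abundance scaling interpolates between reference and background", {
  # at dose 1: mu_vph1 = 150, mu_bg = 7, so mu_vph1 - mu_bg = 143
  cal <- toy_cal(143, 7, 0, 7, 1, 1)
  # r = 43/143 puts the target at 43 + 7 = 50
  expect_equal(scale_to_target_abundance(cal, 43 / 143, 1), 50)
  expect_equal(scale_to_target_abundance(cal, 1, 1), 150)
  expect_equal(scale_to_target_abundance(cal, 1e-12, 1), 7, tolerance = 1e-6)
  expect_error(scale_to_target_abundance(cal, 0, 1), "positive")
  # default reference ratios follow the 143:43:13 brightness proportions
  r <- abundance_ratios()
  expect_equal(unname(r["vph1"]), 1)
  expect_equal(unname(r["cdc12"]), 43 / 143)
  expect_equal(unname(r["whi5"]), 13 / 143)
})

test_that("predicted SNR scales the estimated SNR by the abundance ratio", {
  cal <- toy_cal(2, 30, 0.5, 20, 0.08, 0.7)
  d <- c(2, 11, 40)
  expect_equal(predicted_snr(cal, 1, d), estimate_snr(cal, d))
  # halving r halves the numerator, hence the pSNR, at fixed dose
  expect_equal(predicted_snr(cal, 0.5, d), predicted_snr(cal, 1, d) / 2)
  # brute-force recomputation from the raw lines
  r <- 0.1
  mu_t <- (2 * d + 30 - (0.5 * d + 20)) * r + (0.5 * d + 20)
  expect_equal(predicted_snr(cal, r, d),
               (mu_t - (0.5 * d + 20)) / (0.08 * d + 0.7))
})

test_that("relative brightness is a percent ratio of corrected slopes", {
  gfp <- toy_cal(10, 5, 2, 5, 1, 1)
  expect_equal(relative_brightness(gfp, gfp), 100)
  fp <- toy_cal(18.8, 5, 2, 5, 1, 1)   # corrected slope 16.8 = 2.1 * 8
  expect_equal(relative_brightness(fp, gfp), 210)
  quarter <- toy_cal(52, 0, 2, 0, 1, 1)
  ref200 <- toy_cal(202, 0, 2, 0, 1, 1)
  expect_equal(relative_brightness(quarter, ref200), 25)
  # invariant to camera AU rescaling
  k <- 3.7
  fp_scaled <- toy_cal(18.8 * k, 5 * k, 2 * k, 5 * k, k, k)
  gfp_scaled <- toy_cal(10 * k, 5 * k, 2 * k, 5 * k, k, k)
  expect_equal(relative_brightness(fp_scaled, gfp_scaled), 210)
  expect_error(relative_brightness(fp, toy_cal(2, 0, 2, 0, 1, 1)),
               "positive")
})

test_that("dose for a target SNR solves the linear model", {
  cal <- toy_cal(1, 0, 0, 0, 0.1, 0.5)   # numerator LD, sd 0.1*LD + 0.5
  expect_equal(ld_for_snr(cal, 1, 4), 10 / 3, tolerance = 1e-12)
  expect_equal(ld_for_snr(cal, 1, 0), 0)
  # asymptotic SNR is 1/0.1 = 10: target 12 unattainable
  expect_error(ld_for_snr(cal, 1, 12), class = "infeasible_error")
  # brighter targets need less light (strict monotonicity in r)
  lds <- vapply(c(0.5, 0.6, 0.8, 1), function(r) ld_for_snr(cal, r, 4),
                numeric(1))
  expect_true(all(diff(lds) < 0))
})

test_that("ld_for_snr and predicted_snr round-trip on the feasible domain", {
  cal <- toy_cal(2.2, 40, 0.4, 25, 0.05, 1.1)
  # asymptotic SNR is r * 1.8 / 0.05 = 36 r; stay on the feasible side
  for (r in c(0.3, 1)) {
    for (target in c(1, 4, 9)) {
      ld <- ld_for_snr(cal, r, target)
      if (ld > 0)
        expect_equal(predicted_snr(cal, r, ld), target, tolerance = 1e-9)
      expect_equal(ld_for_snr(cal, r, predicted_snr(cal, r, max(ld, 1))),
                   max(ld, 1), tolerance = 1e-9)
    }
  }
  # below the feasibility boundary the solver refuses
  expect_error(ld_for_snr(cal, 0.0909, 4), class = "infeasible_error")
})

test_that("objective scaling follows NA^4 over magnification squared", {
  x40 <- objective_spec(40, 1.3); x60 <- objective_spec(60, 1.3)
  expect_equal(objective_snr_scaling(x40, x60), 1 / 2.25)
  expect_equal(objective_snr_scaling(x40, x40), 1)
  expect_equal(objective_snr_scaling(objective_spec(40, 1),
                                     objective_spec(40, 1.3)),
               1.3^4)
  expect_error(objective_spec(-40, 1.3), "positive")
})

test_that("growth rate at an SNR target composes calibration and morbidity", {
  # per-acquisition dose for SNR 4 is 50; at a 60-min interval the hourly
  # rate is also 50, and with ED50 = 100, tau = 2 the growth fraction is 0.8
  cal <- toy_cal(1, 0, 0, 0, 0, 12.5)    # constant noise: LD/12.5 = 4 at 50
  fit <- toy_fit(gr0 = 0.49, ed50 = 100, tau = 2)
  res <- gr_at_snr_target(cal, 1, 4, fit, interval_min = 60)
  expect_equal(res$ld_per_acq, 50)
  expect_equal(res$dose_rate, 50)
  expect_equal(res$gr_fraction, 0.8)
  # dose below the NOEL implies a fraction of at least 0.98
  cheap <- gr_at_snr_target(toy_cal(1, 0, 0, 0, 0, 0.5), 1, 4, fit,
                            interval_min = 60)
  expect_lt(cheap$dose_rate, noel(fit))
  expect_gte(cheap$gr_fraction, 0.98)
  # interval conversion: 5-min imaging applies 12 acquisitions per hour
  res5 <- gr_at_snr_target(cal, 1, 4, fit, interval_min = 5)
  expect_equal(res5$dose_rate, 50 * 12)
})

test_that("predicted SNR from a reference ratio reproduces direct measurement in simulation", {
  # generate vph1-level and whi5-level strains with consistent abundances
  base <- synthetic_channel_model(probe_rate = 14.3, background_rate = 2,
                                  camera_floor = 100, cell_cv = 0.08)
  whi5 <- synthetic_channel_model(probe_rate = 14.3 * 13 / 143,
                                  background_rate = 2,
                                  camera_floor = 100, cell_cv = 0.08)
  doses <- c(0, 10, 20, 40, 80, 160)
  cal_ref <- fit_channel_calibration(
    simulate_intensity_measurements(base, doses, n_cells = 4000, seed = 31))
  cal_dir <- fit_channel_calibration(
    simulate_intensity_measurements(whi5, doses, n_cells = 4000, seed = 32))
  at <- 120
  psnr <- predicted_snr(cal_ref, 13 / 143, at)
  # direct eSNR uses the dim strain's own (larger-relative) noise line, so
  # compare numerators: background-corrected predicted signal
  direct <- scale_to_target_abundance(cal_dir, 1, at) -
    (cal_dir$bg_slope * at + cal_dir$bg_intercept)
  viaref <- scale_to_target_abundance(cal_ref, 13 / 143, at) -
    (cal_ref$bg_slope * at + cal_ref$bg_intercept)
  expect_equal(viaref, direct, tolerance = 0.1)
  expect_gt(psnr, 0)
})
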