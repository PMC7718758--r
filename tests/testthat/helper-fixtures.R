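# Hand-built model objects used across tests.

# dose-effect fit with known parameters (bypasses fitting)
toy_fit <- function(gr0 = 1, ed50 = 290, tau = 1.8, noel_fraction = 0.98) {
  fit <- structure(list(gr0 = gr0, ed50 = ed50, tau = tau,
                        noel_fraction = noel_fraction, normalized = TRUE),
                   class = "dose_response_fit")
  fit$noel <- noel(fit, noel_fraction)
  fit
}

# calibration with known lines (bypasses fitting)
toy_cal <- function(sig_slope, sig_intercept, bg_slope, bg_intercept,
                    sd_slope, sd_intercept, fluorophore = "toy") {
  structure(list(fluorophore = fluorophore, channel = NULL,
                 reference_target = "Vph1",
                 sig_slope = sig_slope, sig_intercept = sig_intercept,
                 bg_slope = bg_slope, bg_intercept = bg_intercept,
                 sd_slope = sd_slope, sd_intercept = sd_intercept),
            class = "channel_calibration")
}

# bleach fit with known parameters
toy_bleach <- function(a, b, c = 0, d = 0) {
  structure(list(a = a, b = b, c = c, d = d), class = "bleach_fit")
}

# noiseless dose-response points from the sigmoidal law
hill_points <- function(gr0, ed50, tau,
                        doses = c(0, 30, 60, 120, 240, 480, 960)) {
  data.frame(dose = doses, gr = gr0 / (1 + (doses / ed50)^tau))
}
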