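#' Configuration for a synthetic photomorbidity experiment
#'
#' Defines the experimental design emulated by [simulate_pad_counts()]: the
#' default mirrors the standard photomorbidity assay — 6 light doses plus an
#' unilluminated control, 5 pads per condition (35 pads), 100 frames at 5 min
#' intervals (0-495 min), a control doubling time of 123 min, and a cyan
#' dose-effect truth of ED50 = 290 J cm^-2 h^-1 with tau = 1.8.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_pads Pads per condition.
#' @param doses Dose rates (J cm^-2 h^-1) including 0 (control).
#' @param gr0 Control growth rate, doublings h^-1.
#' @param ed50,tau Dose-effect truth.
#' @param noise_sd sdlog of multiplicative lognormal observation noise on
#'   counts.
#' @param onset_delay Optional delay (hours) before morbidity manifests at
#'   sub-ED50 doses; `NULL` for instantaneous onset.
#' @param capacity Cell count above which a pad is flagged excluded (colony
#'   outgrew the field of view).
#' @param n0 Initial cells per pad.
#' @param t_max,interval Observation window and frame interval, minutes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_pads = 5,
                              doses = c(0, 18, 36, 72, 145, 290, 580),
                              gr0 = 60 / 123, ed50 = 290, tau = 1.8,
                              noise_sd = 0.05, onset_delay = NULL,
                              capacity = 5000, n0 = 8,
                              t_max = 495, interval = 5) {
  if (!0 %in% doses) stop("`doses` must include 0 (control)", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (capacity <= n0) stop("`capacity` must exceed `n0`", call. = FALSE)
  stopifnot(n_pads >= 1, gr0 > 0, ed50 > 0, tau > 0, noise_sd >= 0,
            t_max > 0, interval > 0)
  structure(list(seed = as.integer(seed), n_pads = n_pads, doses = doses,
                 gr0 = gr0, ed50 = ed50, tau = tau, noise_sd = noise_sd,
                 onset_delay = onset_delay, capacity = capacity, n0 = n0,
                 t_max = t_max, interval = interval),
            class = "simulation_config")
}

#' Simulate pad-level cell-count time series across light doses
#'
#' For each dose and pad, counts follow N(t) = n0 * 2^(GR(dose) * t) with
#' GR(dose) from the sigmoidal dose-effect law, multiplied by lognormal
#' observation noise and rounded to integers (>= 1). With an `onset_delay`,
#' sub-ED50 doses grow at the control rate until the delay and at the
#' dose-reduced rate thereafter, mimicking the delayed onset of
#' photomorbidity. Pads whose count exceeds `capacity` are flagged excluded.
#'
#' @param config A [simulation_config()].
#' @return Named list (one element per dose, names = dose values) of lists
#'   of [pad_counts()]; the truth and config are attached as attributes.
#' @export
simulate_pad_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  times <- seq(0, config$t_max, by = config$interval)
  gr0_min <- config$gr0 / 60
  out <- lapply(config$doses, function(d) {
    gr_d <- (config$gr0 / (1 + (d / config$ed50)^config$tau)) / 60
    td_min <- if (!is.null(config$onset_delay) && d > 0 && d < config$ed50)
      config$onset_delay * 60 else 0
    expected <- config$n0 *
      2^(gr0_min * pmin(times, td_min) + gr_d * pmax(0, times - td_min))
    lapply(seq_len(config$n_pads), function(p) {
      noisy <- expected *
        stats::rlnorm(length(times), meanlog = 0, sdlog = config$noise_sd)
      counts <- pmax(1, round(noisy))
      counts[1] <- config$n0   # loading count is observed exactly
      pad_counts(sprintf("d%g_p%d", d, p), times, counts,
                 excluded = any(counts > config$capacity))
    })
  })
  names(out) <- as.character(config$doses)
  attr(out, "config") <- config
  out
}

#' Dose-response table from simulated (or real) pads
#'
#' Computes one growth rate per pad with [growth_rate_endpoint()] (or
#' [growth_rate_expfit()]) and returns the long (dose, gr) table ready for
#' [fit_dose_response()]. Excluded pads are dropped.
#'
#' @param pads_by_dose Named list of pad lists as returned by
#'   [simulate_pad_counts()] (names are dose values).
#' @param method `"endpoint"` or `"expfit"`.
#' @return Data frame with columns `dose` and `gr` (doublings h^-1).
#' @export
pads_to_dose_response <- function(pads_by_dose,
                                  method = c("endpoint", "expfit")) {
  method <- match.arg(method)
  grf <- switch(method, endpoint = growth_rate_endpoint,
                expfit = growth_rate_expfit)
  rows <- lapply(names(pads_by_dose), function(d) {
    keep <- Filter(function(p) !p$excluded, pads_by_dose[[d]])
    if (length(keep) == 0L) return(NULL)
    data.frame(dose = as.numeric(d),
               gr = vapply(keep, function(p) grf(p)$growth_rate_per_h,
                           numeric(1)))
  })
  do.call(rbind, rows)
}

#' Synthetic fluorescence channel model
#'
#' Generative model of the fluorescent signal: mean signal at dose LD is
#' (B + P) * LD * QE + NR2 and mean background is B * LD * QE + NR2, with P
#' the probe photon rate, B the background (autofluorescence + media) rate,
#' QE the detector quantum efficiency and NR2 the camera noise floor.
#' Per-cell intensities scatter around the mean with coefficient of
#' variation `cell_cv`.
#'
#' @param probe_rate,background_rate AU per unit dose.
#' @param qe Detector quantum efficiency (dimensionless).
#' @param camera_floor Camera noise floor NR2, AU.
#' @param cell_cv Coefficient of variation of per-cell signal.
#' @return A `synthetic_channel_model`.
#' @export
synthetic_channel_model <- function(probe_rate, background_rate, qe = 1,
                                    camera_floor = 100, cell_cv = 0.1) {
  stopifnot(probe_rate >= 0, background_rate >= 0, qe >= 0,
            camera_floor >= 0, cell_cv >= 0)
  structure(list(probe_rate = probe_rate, background_rate = background_rate,
                 qe = qe, camera_floor = camera_floor, cell_cv = cell_cv),
            class = "synthetic_channel_model")
}

#' Simulate population fluorescence summaries across light doses
#'
#' Draws `n_cells` per-cell intensities per dose for the tagged strain (mean
#' (B+P)*LD*QE + NR2) and the untagged parent (mean B*LD*QE + NR2), both
#' Gaussian with the model's cell-to-cell CV, and summarizes them as means
#' and SDs — the input format of [fit_channel_calibration()].
#'
#' @param model A [synthetic_channel_model()].
#' @param doses Light doses (calibration units).
#' @param n_cells Cells per dose.
#' @param seed Integer seed.
#' @return Data frame with columns `dose`, `mean_signal`, `mean_background`,
#'   `sd_signal`, `sd_background`, `n_cells`.
#' @export
simulate_intensity_measurements <- function(model, doses, n_cells = 500,
                                            seed = 1) {
  stopifnot(inherits(model, "synthetic_channel_model"))
  set.seed(seed)
  rows <- lapply(doses, function(d) {
    mu_sig <- (model$background_rate + model$probe_rate) * d * model$qe +
      model$camera_floor
    mu_bg <- model$background_rate * d * model$qe + model$camera_floor
    sig <- stats::rnorm(n_cells, mu_sig, model$cell_cv * mu_sig)
    bg <- stats::rnorm(n_cells, mu_bg, model$cell_cv * mu_bg)
    data.frame(dose = d, mean_signal = mean(sig), mean_background = mean(bg),
               sd_signal = stats::sd(sig), sd_background = stats::sd(bg),
               n_cells = n_cells)
  })
  do.call(rbind, rows)
}

#' Simulate a photobleaching trace
#'
#' Samples the two-term decay a*exp(b*x) + c*exp(d*x) on an even cumulative-
#' dose grid with additive Gaussian noise of SD `noise_sd * (a + c)`. The
#' default of 200 points mirrors a bleaching protocol of 200 acquisitions.
#'
#' @param a,b,c,d Decay parameters (b, d <= 0).
#' @param noise_sd Noise SD as a fraction of the initial intensity.
#' @param n_points Number of points (default 200).
#' @param max_dose Largest cumulative dose on the grid, J cm^-2.
#' @param seed Integer seed.
#' @return Data frame with columns `dose`, `intensity`.
#' @export
simulate_bleach_trace <- function(a, b, c = 0, d = 0, noise_sd = 0.02,
                                  n_points = 200, max_dose, seed = 1) {
  if (b > 0 || d > 0) stop("decay rates must be <= 0", call. = FALSE)
  if (a + c <= 0) stop("initial intensity must be positive", call. = FALSE)
  set.seed(seed)
  dose <- seq(0, max_dose, length.out = n_points)
  y <- a * exp(b * dose) + c * exp(d * dose)
  data.frame(dose = dose,
             intensity = y + stats::rnorm(n_points, 0, noise_sd * (a + c)))
}

#' Simulate single- and pairwise-combined illumination growth fractions
#'
#' Emulates a wavelength-interaction experiment: each single-color condition
#' has a true normalized growth fraction from `single_fractions`; every
#' pairwise combination has true fraction `cdi_true * f_i * f_j`
#' (multiplicative/additive null at `cdi_true = 1`). Observed fractions get
#' additive Gaussian noise and are truncated to (0, 1].
#'
#' @param single_fractions Normalized growth fractions of the single-color
#'   doses, each in (0, 1].
#' @param cdi_true True interaction coefficient (default 1, additive).
#' @param n_reps Replicates per condition.
#' @param noise_sd SD of additive observation noise.
#' @param seed Integer seed.
#' @return List with `singles` (matrix n_reps x n_channels) and `pairs`
#'   (data frame: `a`, `b`, `rep`, `gr_a`, `gr_b`, `gr_combined`).
#' @export
simulate_multicolor <- function(single_fractions, cdi_true = 1,
                                n_reps = 20, noise_sd = 0.02, seed = 1) {
  f <- single_fractions
  if (any(f <= 0) || any(f > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  set.seed(seed)
  k <- length(f)
  obs <- function(mu, n) pmin(1, pmax(1e-6, mu + stats::rnorm(n, 0, noise_sd)))
  singles <- vapply(f, function(mu) obs(mu, n_reps), numeric(n_reps))
  if (is.null(dim(singles))) singles <- matrix(singles, nrow = n_reps)
  colnames(singles) <- paste0("ch", seq_len(k))
  if (k == 1) {
    pairs <- data.frame(a = 1L, b = 1L, rep = seq_len(n_reps),
                        gr_a = singles[, 1], gr_b = 1,
                        gr_combined = singles[, 1])
    return(list(singles = singles, pairs = pairs))
  }
  combs <- utils::combn(k, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1, ci]; j <- combs[2, ci]
    data.frame(a = i, b = j, rep = seq_len(n_reps),
               gr_a = singles[, i], gr_b = singles[, j],
               gr_combined = obs(cdi_true * f[i] * f[j], n_reps))
  }))
  list(singles = singles, pairs = pairs)
}

#' Estimate per-pair CDIs from a simulated interaction experiment
#'
#' @param sim Output of [simulate_multicolor()].
#' @return Data frame with one row per pair: `a`, `b`, `cdi` (computed from
#'   the per-condition mean fractions).
#' @export
estimate_cdis <- function(sim) {
  means <- colMeans(sim$singles)
  agg <- stats::aggregate(gr_combined ~ a + b, data = sim$pairs, FUN = mean)
  agg$cdi <- mapply(function(i, j, gc) cdi(gc, means[i], means[j])$cdi,
                    agg$a, agg$b, agg$gr_combined)
  agg[, c("a", "b", "cdi")]
}
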