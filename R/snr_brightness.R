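#' Measured signal-to-noise ratio
#'
#' SNR = (mu_sig - mu_bg) / noise, where mu_sig is the mean cellular
#' fluorescence of the tagged strain, mu_bg the mean fluorescence of the
#' untagged parent strain (autofluorescence + camera floor), and the noise is
#' an estimate of the statistical fluctuation of the signal. The default mode
#' uses the measured standard deviation of the cellular signal; the
#' `"shot"` mode replaces it with sqrt(mu_sig) (Poisson/shot-noise limit).
#'
#' @param mean_signal,mean_background Mean fluorescence of tagged and
#'   untagged cells, AU.
#' @param sd_signal Standard deviation of the cellular signal, AU; required
#'   in `"sd"` mode.
#' @param mode `"sd"` (default) or `"shot"`.
#' @return Dimensionless SNR (vectorized).
#' @export
measured_snr <- function(mean_signal, mean_background, sd_signal = NULL,
                         mode = c("sd", "shot")) {
  mode <- match.arg(mode)
  noise <- switch(mode,
    sd = {
      if (is.null(sd_signal))
        stop("`sd_signal` is required in mode \"sd\"", call. = FALSE)
      if (any(sd_signal <= 0))
        stop("`sd_signal` must be positive", call. = FALSE)
      sd_signal
    },
    shot = sqrt(mean_signal))
  (mean_signal - mean_background) / noise
}

#' Calibrate signal, background and noise against light dose
#'
#' Signal, background and their fluctuations grow linearly with the applied
#' excitation light dose (plus a camera noise floor at dose 0). This fits
#' three straight lines (a*x + b) to mean signal, mean background and signal
#' SD versus dose by weighted least squares; weights are 1/SD^2 where the
#' corresponding SDs are available and positive, else ordinary least squares.
#'
#' @param measurements Data frame with columns `dose` (J cm^-2 per
#'   acquisition, at the calibration intensity), `mean_signal`,
#'   `mean_background`, `sd_signal` and optionally `sd_background`,
#'   `n_cells`. At least 3 distinct doses required.
#' @param fluorophore Fluorophore label, e.g. `"Citrine"`.
#' @param channel Optional [filter_channel()] the calibration was acquired
#'   in.
#' @param reference_target Name of the tagged reference protein (default
#'   `"Vph1"`).
#' @return A `channel_calibration` with slopes and intercepts `sig_slope`,
#'   `sig_intercept`, `bg_slope`, `bg_intercept`, `sd_slope`, `sd_intercept`.
#' @export
fit_channel_calibration <- function(measurements, fluorophore = "",
                                    channel = NULL,
                                    reference_target = "Vph1") {
  m <- as.data.frame(measurements)
  if (!"dose" %in% names(m) && "dose_J_cm2" %in% names(m))
    names(m)[names(m) == "dose_J_cm2"] <- "dose"
  need <- c("dose", "mean_signal", "mean_background", "sd_signal")
  if (!all(need %in% names(m)))
    stop("`measurements` needs columns ",
         paste(setdiff(need, names(m)), collapse = ", "), call. = FALSE)
  if (length(unique(m$dose)) < 3L)
    stop("need at least 3 distinct doses for calibration", call. = FALSE)
  wfit <- function(y, w) {
    ok <- !is.null(w) && all(is.finite(w)) && all(w > 0)
    if (ok) stats::lm(y ~ dose, data = m, weights = 1 / w^2)
    else stats::lm(y ~ dose, data = m)
  }
  f_sig <- wfit(m$mean_signal, m$sd_signal)
  f_bg <- wfit(m$mean_background, m$sd_background)
  f_sd <- stats::lm(sd_signal ~ dose, data = m)
  co <- function(f) unname(stats::coef(f))
  cal <- structure(list(
    fluorophore = fluorophore, channel = channel,
    reference_target = reference_target,
    sig_slope = co(f_sig)[2], sig_intercept = co(f_sig)[1],
    bg_slope = co(f_bg)[2], bg_intercept = co(f_bg)[1],
    sd_slope = co(f_sd)[2], sd_intercept = co(f_sd)[1],
    measurements = m), class = "channel_calibration")
  if (cal$sig_slope < cal$bg_slope)
    warning("signal slope below background slope: fluorophore not detectable",
            call. = FALSE)
  if (cal$sig_slope < 0 || cal$bg_slope < 0)
    warning("negative fitted slope in calibration", call. = FALSE)
  cal
}

#' @export
print.channel_calibration <- function(x, ...) {
  cat(sprintf("Channel calibration [%s%s], reference %s\n", x$fluorophore,
              if (!is.null(x$channel)) paste0(" @ ", x$channel$name) else "",
              x$reference_target))
  cat(sprintf("  signal:     %.4g * LD + %.4g AU\n", x$sig_slope, x$sig_intercept))
  cat(sprintf("  background: %.4g * LD + %.4g AU\n", x$bg_slope, x$bg_intercept))
  cat(sprintf("  signal SD:  %.4g * LD + %.4g AU\n", x$sd_slope, x$sd_intercept))
  invisible(x)
}

cal_lines <- function(cal, dose, ratio = 1) {
  sig <- cal$sig_slope * dose + cal$sig_intercept
  bg <- cal$bg_slope * dose + cal$bg_intercept
  list(sig = (sig - bg) * ratio + bg, bg = bg,
       sd = cal$sd_slope * dose + cal$sd_intercept)
}

#' Estimated SNR at a light dose from a calibration
#'
#' Evaluates the fitted signal/background/SD lines at `dose` and applies the
#' SNR formula: eSNR(LD) = (mu_sig(LD) - mu_bg(LD)) / sd(LD).
#'
#' @param cal A `channel_calibration`.
#' @param dose Light dose(s), same units as the calibration dose axis.
#' @return Estimated SNR (vectorized).
#' @export
estimate_snr <- function(cal, dose) {
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  l <- cal_lines(cal, dose)
  if (any(l$sd <= 0))
    stop("predicted signal SD is not positive at this dose", call. = FALSE)
  (l$sig - l$bg) / l$sd
}

#' Predict the mean signal of a target protein from a reference calibration
#'
#' Tagging every target with every fluorophore is impractical. Instead, the
#' background-corrected signal of a reference fusion (e.g. Vph1) is scaled by
#' the target:reference abundance ratio measured once with a Citrine fusion
#' set: mu_target = (mu_ref - mu_bg) * r + mu_bg. The ratio r is the
#' background-corrected brightness of the target strain divided by that of
#' the reference strain (r = 1: reference-level expression).
#'
#' @inheritParams estimate_snr
#' @param ratio Abundance ratio r > 0 (see [abundance_ratios()]).
#' @return Predicted mean target signal, AU.
#' @export
scale_to_target_abundance <- function(cal, ratio, dose) {
  if (any(ratio <= 0)) stop("`ratio` must be positive", call. = FALSE)
  cal_lines(cal, dose, ratio)$sig
}

#' Default abundance ratios of the reference fusion set
#'
#' Background-corrected in vivo brightnesses of Citrine fused to Vph1, Cdc12
#' and Whi5 are in proportion 143 : 43 : 13 (AU J^-1 cm^2 h), so relative to
#' Vph1 the abundance ratios are 1, 43/143 and 13/143. The same ratios hold
#' for any fluorophore as long as the signal is discernible from background.
#'
#' @return Named numeric vector of ratios (vph1, cdc12, whi5).
#' @export
abundance_ratios <- function() {
  c(vph1 = 1, cdc12 = 43 / 143, whi5 = 13 / 143)
}

#' Predicted SNR of a target protein at a light dose
#'
#' SNR computed from the abundance-scaled target signal, the channel
#' background line and the channel noise line:
#' pSNR(LD) = r * (mu_ref(LD) - mu_bg(LD)) / sd(LD). With r = 1 this equals
#' [estimate_snr()].
#'
#' @inheritParams scale_to_target_abundance
#' @return Predicted SNR (vectorized).
#' @export
predicted_snr <- function(cal, ratio, dose) {
  if (any(ratio <= 0)) stop("`ratio` must be positive", call. = FALSE)
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  l <- cal_lines(cal, dose, ratio)
  if (any(l$sd <= 0))
    stop("predicted signal SD is not positive at this dose", call. = FALSE)
  (l$sig - l$bg) / l$sd
}

#' In vivo brightness relative to a GFP reference
#'
#' Ratio of background-corrected signal slopes (signal gained per unit light
#' dose) of a fluorophore and the GFP reference calibration, as a percent:
#' 100 * (sig_slope_FP - bg_slope_FP) / (sig_slope_GFP - bg_slope_GFP).
#' Being a ratio of slopes it is invariant to camera gain rescaling.
#'
#' @param cal_fp,cal_ref `channel_calibration` objects for the fluorophore
#'   and the reference (typically eGFP), both on the same reference target.
#' @return Relative brightness in percent (100 = reference).
#' @export
relative_brightness <- function(cal_fp, cal_ref) {
  den <- cal_ref$sig_slope - cal_ref$bg_slope
  if (den <= 0)
    stop("reference has no positive background-corrected slope", call. = FALSE)
  100 * (cal_fp$sig_slope - cal_fp$bg_slope) / den
}

#' Light dose required to reach a target SNR
#'
#' Solves pSNR(LD) = target for the linear calibration model:
#' (r * dS * LD + r * dI) / (sd_slope * LD + sd_intercept) = target, with
#' dS = sig_slope - bg_slope and dI = sig_intercept - bg_intercept. The
#' target is unattainable when it exceeds the asymptotic SNR
#' r * dS / sd_slope; then an error of class `infeasible_error` is thrown.
#'
#' @inheritParams scale_to_target_abundance
#' @param target_snr Target SNR > 0 (default 4, the lowest SNR giving robust
#'   quantification of cellular fluorescence).
#' @return Smallest non-negative dose reaching the target, in calibration
#'   dose units.
#' @export
ld_for_snr <- function(cal, ratio = 1, target_snr = 4) {
  if (target_snr < 0) stop("`target_snr` must be non-negative", call. = FALSE)
  dS <- (cal$sig_slope - cal$bg_slope) * ratio
  dI <- (cal$sig_intercept - cal$bg_intercept) * ratio
  num <- target_snr * cal$sd_intercept - dI
  den <- dS - target_snr * cal$sd_slope
  infeasible <- function(msg)
    stop(structure(class = c("infeasible_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  if (den <= 0)
    infeasible(sprintf(
      "SNR %g unattainable: asymptotic SNR is %.4g", target_snr,
      if (cal$sd_slope > 0) dS / cal$sd_slope else Inf))
  ld <- num / den
  if (ld < 0) ld <- 0   # target already met at dose 0
  if (predicted_snr(cal, ratio, ld) < target_snr - 1e-9)
    infeasible(sprintf("SNR %g unattainable within the linear model", target_snr))
  ld
}

#' Microscope objective specification
#'
#' @param magnification Objective magnification (e.g. 40).
#' @param na Numerical aperture.
#' @return An `objective_spec`.
#' @export
objective_spec <- function(magnification, na) {
  if (magnification <= 0 || na <= 0)
    stop("magnification and NA must be positive", call. = FALSE)
  structure(list(magnification = magnification, na = na),
            class = "objective_spec")
}

#' SNR scaling between objectives
#'
#' Widefield SNR scales as NA^4 / M^2. Returns the multiplicative factor the
#' SNR changes by when switching `from` one objective `to` another:
#' (NA_to/NA_from)^4 * (M_from/M_to)^2. E.g. 40x -> 60x at equal NA gives
#' (40/60)^2 = 1/2.25, a 2.25-fold SNR decrease.
#'
#' @param from,to `objective_spec` objects.
#' @return Dimensionless SNR ratio (to/from).
#' @export
objective_snr_scaling <- function(from, to) {
  stopifnot(inherits(from, "objective_spec"), inherits(to, "objective_spec"))
  (to$na / from$na)^4 * (from$magnification / to$magnification)^2
}

#' Expected growth-rate fraction at the dose reaching a target SNR
#'
#' Composes the SNR calibration with a photomorbidity dose-effect curve:
#' finds the per-acquisition light dose at which the target protein reaches
#' `target_snr`, converts it to a per-hour dose rate at the stated imaging
#' interval, and evaluates the morbidity curve there. The returned fraction
#' is the growth rate relative to the unilluminated control expected while
#' imaging this target at the target SNR.
#'
#' The morbidity fit should be the dose-effect curve whose central
#' wavelength is closest to the channel's excitation band; for red channels
#' the green curve gives a conservative (pessimistic) estimate.
#'
#' @inheritParams ld_for_snr
#' @param morbidity_fit A `dose_response_fit` for the excitation wavelength.
#' @param interval_min Imaging interval, minutes (default 5).
#' @return List with `ld_per_acq` (J cm^-2 per acquisition), `dose_rate`
#'   (J cm^-2 h^-1) and `gr_fraction` (growth rate / control).
#' @export
gr_at_snr_target <- function(cal, ratio, target_snr, morbidity_fit,
                             interval_min = 5) {
  ld <- ld_for_snr(cal, ratio, target_snr)
  rate <- ld * 60 / interval_min
  frac <- predict_gr(morbidity_fit, rate) / morbidity_fit$gr0
  list(ld_per_acq = ld, dose_rate = rate, gr_fraction = frac)
}
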