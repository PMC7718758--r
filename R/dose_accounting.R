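#' Illumination settings for one excitation channel
#'
#' Bundles the microscope settings that determine the excitation light dose a
#' sample receives in time-lapse imaging: light intensity at the sample plane,
#' set exposure time, the hardware exposure delay of the setup, and the imaging
#' interval. The hardware delay is the extra time the sample is illuminated
#' beyond the set exposure due to shutter/trigger latency; it must be measured
#' for each setup (the default of 0.187 s is typical for a triggered LED
#' light engine) and is added to every exposure.
#'
#' @param channel Channel name, e.g. `"cyan"`.
#' @param intensity_mw_cm2 Excitation intensity at the sample plane, mW cm^-2.
#' @param set_exposure_s Set (software) exposure time, seconds.
#' @param interval_min Imaging interval, minutes between acquisitions.
#' @param hardware_delay_s Additional exposure time due to hardware delays,
#'   seconds. Default 0.187.
#' @return An object of class `illumination_settings`.
#' @examples
#' cyan <- illumination_settings("cyan", 3.7, 0.5, interval_min = 5)
#' effective_exposure(cyan)
#' dose_rate(cyan)
#' @export
illumination_settings <- function(channel, intensity_mw_cm2, set_exposure_s,
                                  interval_min, hardware_delay_s = 0.187) {
  stopifnot(is.character(channel), length(channel) == 1L)
  if (!is.numeric(intensity_mw_cm2) || intensity_mw_cm2 < 0)
    stop("`intensity_mw_cm2` must be a non-negative number", call. = FALSE)
  if (!is.numeric(set_exposure_s) || set_exposure_s < 0)
    stop("`set_exposure_s` must be a non-negative number", call. = FALSE)
  if (!is.numeric(hardware_delay_s) || hardware_delay_s < 0)
    stop("`hardware_delay_s` must be a non-negative number", call. = FALSE)
  if (!is.numeric(interval_min) || interval_min <= 0)
    stop("`interval_min` must be positive", call. = FALSE)
  if ((set_exposure_s + hardware_delay_s) >= interval_min * 60)
    stop("effective exposure must be shorter than the imaging interval",
         call. = FALSE)
  structure(
    list(channel = channel,
         intensity_mw_cm2 = as.numeric(intensity_mw_cm2),
         set_exposure_s = as.numeric(set_exposure_s),
         hardware_delay_s = as.numeric(hardware_delay_s),
         interval_min = as.numeric(interval_min)),
    class = "illumination_settings")
}

#' @export
print.illumination_settings <- function(x, ...) {
  cat(sprintf(
    "Illumination settings [%s]: %.3g mW cm-2, %.3g s (+%.3g s delay) every %.3g min\n",
    x$channel, x$intensity_mw_cm2, x$set_exposure_s, x$hardware_delay_s,
    x$interval_min))
  cat(sprintf("  dose rate: %.4g J cm-2 h-1\n", dose_rate(x)))
  invisible(x)
}

#' Effective exposure time
#'
#' The time the sample is actually illuminated per acquisition: the set
#' exposure plus the setup's hardware delay.
#'
#' @param settings An [illumination_settings()] object.
#' @return Effective exposure in seconds.
#' @export
effective_exposure <- function(settings) {
  stopifnot(inherits(settings, "illumination_settings"))
  settings$set_exposure_s + settings$hardware_delay_s
}

#' Light dose rate of an imaging channel
#'
#' Computes the light dose applied per hour, LD = I * tE / tInt, from the
#' intensity I (converted to W cm^-2), the delay-corrected effective exposure
#' tE (s) and the number of acquisitions per hour (60 / interval).
#'
#' The brightfield illumination contributes a dose typically ~50-fold below
#' the weakest fluorescence excitation dose and is ignored by default; pass a
#' measured rate via `brightfield_rate` to add it.
#'
#' @inheritParams effective_exposure
#' @param brightfield_rate Optional additive brightfield dose rate,
#'   J cm^-2 h^-1. Default 0.
#' @return Dose rate in J cm^-2 h^-1.
#' @export
dose_rate <- function(settings, brightfield_rate = 0) {
  stopifnot(inherits(settings, "illumination_settings"))
  if (!is.numeric(brightfield_rate) || brightfield_rate < 0)
    stop("`brightfield_rate` must be non-negative", call. = FALSE)
  (settings$intensity_mw_cm2 / 1000) * effective_exposure(settings) *
    (60 / settings$interval_min) + brightfield_rate
}

#' Cumulative light dose
#'
#' @param rate Dose rate, J cm^-2 h^-1.
#' @param duration_h Illumination duration, hours.
#' @return Cumulative dose in J cm^-2.
#' @export
cumulative_dose <- function(rate, duration_h) {
  if (any(rate < 0) || any(duration_h < 0))
    stop("`rate` and `duration_h` must be non-negative", call. = FALSE)
  rate * duration_h
}

#' Light dose per doubling time
#'
#' Normalizes a per-hour dose rate to the population doubling time, giving the
#' dose a cell lineage accumulates per cell cycle. Cells tolerate a fixed dose
#' per cell cycle when growth is slowed by temperature, which makes this the
#' natural scale for comparing conditions with different growth rates.
#'
#' @param rate Dose rate, J cm^-2 h^-1.
#' @param doubling_time_min Doubling time, minutes.
#' @return Dose in J cm^-2 per doubling time.
#' @export
dose_per_doubling <- function(rate, doubling_time_min) {
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  if (any(doubling_time_min <= 0))
    stop("`doubling_time_min` must be positive", call. = FALSE)
  rate * doubling_time_min / 60
}

#' Excitation filter channel
#'
#' Describes an excitation band by its center wavelength and bandwidth, named
#' by perceived color as is conventional (e.g. cyan = 480/20 nm), together
#' with the key of the photomorbidity dose-effect curve that applies to it.
#' Because photomorbidity depends on the central wavelength but not on the
#' filter bandwidth, channels without their own morbidity curve are mapped to
#' the measured curve with the closest central wavelength (for red channels
#' the green curve, a conservative choice since green light is more morbid).
#'
#' @param name Channel name.
#' @param center_nm Center wavelength, nm.
#' @param bandwidth_nm Filter bandwidth (FWHM), nm.
#' @param morbidity_curve_key Key of the dose-effect curve used for this
#'   channel; defaults to `name`.
#' @return An object of class `filter_channel`.
#' @export
filter_channel <- function(name, center_nm, bandwidth_nm,
                           morbidity_curve_key = name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(center_nm) || center_nm <= 0)
    stop("`center_nm` must be positive", call. = FALSE)
  if (!is.numeric(bandwidth_nm) || bandwidth_nm <= 0)
    stop("`bandwidth_nm` must be positive", call. = FALSE)
  structure(
    list(name = name, center_nm = as.numeric(center_nm),
         bandwidth_nm = as.numeric(bandwidth_nm),
         morbidity_curve_key = morbidity_curve_key),
    class = "filter_channel")
}

#' @export
print.filter_channel <- function(x, ...) {
  cat(sprintf("Filter channel %s (%g/%g nm), morbidity curve: %s\n",
              x$name, x$center_nm, x$bandwidth_nm, x$morbidity_curve_key))
  invisible(x)
}
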