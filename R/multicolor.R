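#' Coefficient of drug interaction for two excitation wavelengths
#'
#' CDI = GR_AB / (GR_A * GR_B), where GR_AB is the control-normalized growth
#' rate under combined illumination and GR_A, GR_B the normalized growth
#' rates of the single-color doses. CDI ~ 1 means the morbid effects of the
#' two wavelengths combine independently (additive / Bliss independence);
#' CDI < 0.8 indicates synergy, CDI > 1.2 antagonism (conventional
#' pharmacology thresholds, configurable).
#'
#' @param gr_combined Normalized growth rate under combined illumination,
#'   in (0, 1].
#' @param gr_a,gr_b Normalized growth rates of the single-color doses, in
#'   (0, 1].
#' @param thresholds Length-2 numeric `c(synergy, antagonism)` classification
#'   cutoffs; default `c(0.8, 1.2)`.
#' @return An `interaction_result` with elements `cdi` and `classification`.
#' @export
cdi <- function(gr_combined, gr_a, gr_b, thresholds = c(0.8, 1.2)) {
  vals <- c(gr_combined, gr_a, gr_b)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 1))
    stop("growth fractions must lie in (0, 1]", call. = FALSE)
  value <- gr_combined / (gr_a * gr_b)
  cls <- if (value < thresholds[1]) "synergistic"
         else if (value > thresholds[2]) "antagonistic"
         else "additive"
  structure(list(cdi = value, classification = cls),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("CDI = %.3g (%s)\n", x$cdi, x$classification))
  invisible(x)
}

#' Per-channel growth-rate budget for multi-color NOEL imaging
#'
#' Under additivity the combined growth fraction is the product of the
#' per-wavelength fractions, so to keep the combined effect above the NOEL
#' each of n distinct excitation wavelengths must individually allow a
#' growth fraction of at least noel_fraction^(1/n) (e.g. 0.98^(1/3) = 0.993
#' for three colors).
#'
#' @param n_channels Number of distinct excitation wavelengths (>= 1).
#' @param noel_fraction Overall NOEL growth fraction, default 0.98.
#' @return Per-channel growth-rate fraction budget.
#' @export
per_channel_budget <- function(n_channels, noel_fraction = 0.98) {
  if (n_channels < 1) stop("`n_channels` must be >= 1", call. = FALSE)
  noel_fraction^(1 / n_channels)
}

#' Combined growth fraction under the additive model
#'
#' @param fractions Per-wavelength normalized growth fractions, each in
#'   (0, 1].
#' @return Product of the fractions.
#' @export
predict_combined_gr <- function(fractions) {
  if (length(fractions) == 0)
    stop("`fractions` must be non-empty", call. = FALSE)
  if (any(fractions <= 0) || any(fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  prod(fractions)
}

#' Maximum dose rate satisfying a growth-rate budget
#'
#' Inverts the photomorbidity curve at a budget fraction: the largest light
#' dose rate a channel may apply while keeping its growth-rate fraction at
#' or above the budget.
#'
#' @param fit A `dose_response_fit` for the channel's excitation wavelength.
#' @param budget_fraction Growth fraction budget in (0, 1).
#' @return Dose rate in J cm^-2 h^-1.
#' @export
max_ld_at_budget <- function(fit, budget_fraction) {
  invert_dose(fit, budget_fraction)
}

#' Plan a multi-color imaging configuration under additive photomorbidity
#'
#' For each candidate channel, computes the light dose needed to image its
#' target at `target_snr`, converts it to a per-hour dose rate at the
#' imaging interval, and compares it against the per-wavelength budget dose
#' implied by the additive NOEL model. Channels sharing one excitation band
#' (same `band` key) have their doses summed against a single budget, since
#' photomorbidity depends on the wavelength, not on which fluorophore is
#' being excited; the number of *distinct* bands sets the per-band budget
#' noel_fraction^(1/n).
#'
#' @param candidates Named list of channels; each element a list with
#'   `cal` (a `channel_calibration`), `ratio` (target abundance ratio),
#'   `fit` (the `dose_response_fit` of the excitation band) and optionally
#'   `band` (excitation-band key; defaults to the element's name) and
#'   `fluorophore`.
#' @param target_snr Target SNR per channel (default 4).
#' @param interval_min Imaging interval in minutes (default 5).
#' @param noel_fraction Overall NOEL growth fraction (default 0.98).
#' @return A `multicolor_plan`: per-channel table (`channels`), per-band
#'   budget table (`bands`, with budget dose, applied dose and slack),
#'   `combined_gr_fraction` and `feasible`.
#' @export
plan_channels <- function(candidates, target_snr = 4, interval_min = 5,
                          noel_fraction = 0.98) {
  stopifnot(is.list(candidates), length(candidates) >= 1)
  nm <- names(candidates)
  if (is.null(nm) || any(nm == ""))
    stop("`candidates` must be a named list", call. = FALSE)

  ch <- do.call(rbind, lapply(nm, function(k) {
    cand <- candidates[[k]]
    band <- if (is.null(cand$band)) k else cand$band
    ld <- tryCatch(ld_for_snr(cand$cal, cand$ratio, target_snr),
                   infeasible_error = function(e) NA_real_)
    data.frame(channel = k, band = band,
               fluorophore = if (is.null(cand$fluorophore))
                 cand$cal$fluorophore else cand$fluorophore,
               ratio = cand$ratio,
               ld_per_acq = ld,
               dose_rate = ld * 60 / interval_min,
               snr_feasible = !is.na(ld),
               stringsAsFactors = FALSE)
  }))

  bands <- unique(ch$band)
  n_bands <- length(bands)
  budget_fraction <- per_channel_budget(n_bands, noel_fraction)
  band_rows <- do.call(rbind, lapply(bands, function(b) {
    idx <- which(ch$band == b)
    fit <- candidates[[nm[min(which(ch$band == b))]]]$fit
    applied <- sum(ch$dose_rate[idx])
    budget_dose <- max_ld_at_budget(fit, budget_fraction)
    frac <- if (is.finite(applied)) {
      if (applied > 0) predict_gr(fit, applied) / fit$gr0 else 1
    } else NA_real_
    data.frame(band = b, n_channels = length(idx),
               applied_dose_rate = applied, budget_dose_rate = budget_dose,
               slack = budget_dose - applied,
               gr_fraction = frac,
               within_budget = is.finite(applied) && applied <= budget_dose,
               stringsAsFactors = FALSE)
  }))
  ch$predicted_snr <- ifelse(ch$snr_feasible, target_snr, NA_real_)
  combined <- if (all(is.finite(band_rows$gr_fraction)))
    prod(band_rows$gr_fraction) else NA_real_
  feasible <- all(ch$snr_feasible) && all(band_rows$within_budget) &&
    is.finite(combined) && combined >= noel_fraction - 1e-9
  structure(list(channels = ch, bands = band_rows,
                 budget_fraction = budget_fraction,
                 combined_gr_fraction = combined,
                 noel_fraction = noel_fraction,
                 target_snr = target_snr, interval_min = interval_min,
                 feasible = feasible,
                 infeasible_channels = ch$channel[!ch$snr_feasible]),
            class = "multicolor_plan")
}

#' @export
print.multicolor_plan <- function(x, ...) {
  cat(sprintf("Multi-color plan: %d channel(s) in %d excitation band(s)\n",
              nrow(x$channels), nrow(x$bands)))
  cat(sprintf("  per-band budget fraction: %.4g (overall NOEL %.3g)\n",
              x$budget_fraction, x$noel_fraction))
  cat(sprintf("  combined growth fraction: %.4g\n", x$combined_gr_fraction))
  cat(sprintf("  feasible: %s\n", x$feasible))
  if (length(x$infeasible_channels))
    cat("  SNR unattainable for:",
        paste(x$infeasible_channels, collapse = ", "), "\n")
  invisible(x)
}
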