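#' Sigmoidal photomorbidity dose-effect model
#'
#' Growth rate as a function of light dose rate:
#' GR(LD) = GR0 / (1 + (LD/ED50)^tau). ED50 is the dose rate halving the
#' growth rate; tau measures how abruptly morbidity sets in once the dose
#' exceeds the tolerable level (large tau: threshold-like onset).
#'
#' @param fit A `dose_response_fit` (from [fit_dose_response()]) or a list
#'   with elements `gr0`, `ed50`, `tau`.
#' @param dose Light dose rate(s), J cm^-2 h^-1, non-negative.
#' @return Predicted growth rate(s), same units as the fitted growth rates.
#' @export
predict_gr <- function(fit, dose) {
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  fit$gr0 / (1 + (dose / fit$ed50)^fit$tau)
}

lad_objective <- function(par, .dose, .gr) {
  # par = (gr0, log ed50, log tau)
  pred <- par[1] / (1 + (.dose / exp(par[2]))^exp(par[3]))
  sum(abs(.gr - pred))
}

fit_lad_once <- function(dose, gr, start, maxit = 2000) {
  stats::optim(start, lad_objective, .dose = dose, .gr = gr,
               method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
}

#' Fit the sigmoidal dose-effect curve by least absolute deviations
#'
#' Fits GR(LD) = GR0 / (1 + (LD/ED50)^tau) to (dose rate, growth rate) points
#' by minimizing the sum of absolute residuals — a robust criterion that
#' tolerates occasional outlier pads. Optimization uses a derivative-free
#' Nelder-Mead simplex with multiple starts (ED50 at the median and the
#' maximum tested dose, tau in 1, 2, 4) and a polish restart from the best
#' solution.
#'
#' @param data Data frame with columns `dose` (J cm^-2 h^-1) and `gr`
#'   (growth rate; absolute or control-normalized). Columns named
#'   `dose_J_cm2_h` / `growth_rate` are also accepted. Must contain dose-0
#'   controls and at least 4 distinct dose levels.
#' @param normalize If `TRUE` (default) growth rates are divided by the mean
#'   dose-0 growth rate before fitting, so GR0 is ~1 and fits are comparable
#'   across experiments.
#' @param noel_fraction Growth-rate fraction defining the NOEL; default 0.98.
#' @return A `dose_response_fit` with elements `gr0`, `ed50`, `tau`, `noel`,
#'   `noel_fraction`, `objective` (LAD criterion at the optimum),
#'   `convergence`, `data` and `normalized`.
#' @seealso [noel()], [invert_dose()], [bootstrap_ci()]
#' @export
fit_dose_response <- function(data, normalize = TRUE, noel_fraction = 0.98) {
  data <- as.data.frame(data)
  if (!"dose" %in% names(data) && "dose_J_cm2_h" %in% names(data))
    names(data)[names(data) == "dose_J_cm2_h"] <- "dose"
  if (!"gr" %in% names(data) && "growth_rate" %in% names(data))
    names(data)[names(data) == "growth_rate"] <- "gr"
  if (!all(c("dose", "gr") %in% names(data)))
    stop("`data` needs columns `dose` and `gr`", call. = FALSE)
  dose <- as.numeric(data$dose); gr <- as.numeric(data$gr)
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct dose levels to fit", call. = FALSE)
  if (normalize) {
    if (!any(dose == 0))
      stop("normalized fits require dose-0 control points", call. = FALSE)
    gr0_ctrl <- mean(gr[dose == 0])
    if (gr0_ctrl <= 0) stop("control growth rate must be positive", call. = FALSE)
    gr <- gr / gr0_ctrl
  }
  if (diff(range(gr)) == 0)
    stop("all growth rates are equal; tau is unidentifiable (degenerate fit)",
         call. = FALSE)

  gr0_start <- if (any(dose == 0)) mean(gr[dose == 0]) else max(gr)
  dpos <- dose[dose > 0]
  best <- NULL
  for (ed in c(stats::median(dpos), max(dpos))) {
    for (tau in c(1, 2, 4)) {
      res <- fit_lad_once(dose, gr, c(gr0_start, log(ed), log(tau)))
      if (is.null(best) || res$value < best$value) best <- res
    }
  }
  # polish: restart the simplex from the incumbent (fresh simplex geometry)
  for (i in 1:2) {
    res <- fit_lad_once(dose, gr, best$par)
    if (res$value < best$value) best <- res
  }
  fit <- structure(list(
    gr0 = best$par[1], ed50 = exp(best$par[2]), tau = exp(best$par[3]),
    noel_fraction = noel_fraction, objective = best$value,
    convergence = best$convergence,
    data = data.frame(dose = dose, gr = gr), normalized = normalize),
    class = "dose_response_fit")
  fit$noel <- noel(fit, noel_fraction)
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Photomorbidity dose-effect fit (least absolute deviations)\n")
  cat(sprintf("  GR0  = %.4g%s\n", x$gr0,
              if (x$normalized) " (control-normalized)" else ""))
  cat(sprintf("  ED50 = %.4g J cm-2 h-1\n", x$ed50))
  cat(sprintf("  tau  = %.4g\n", x$tau))
  cat(sprintf("  NOEL (%.0f%% of control) = %.4g J cm-2 h-1\n",
              100 * x$noel_fraction, x$noel))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI ED50: [%.4g, %.4g], tau: [%.4g, %.4g], NOEL: [%.4g, %.4g]\n",
                x$ci["ed50", 1], x$ci["ed50", 2], x$ci["tau", 1],
                x$ci["tau", 2], x$ci["noel", 1], x$ci["noel", 2]))
  }
  invisible(x)
}

#' No-observed-effect level of a dose-effect fit
#'
#' The NOEL is the light dose rate at which the growth rate falls to
#' `fraction` (default 98%) of the control; below it no growth effect is
#' experimentally detectable. Closed form from the model:
#' NOEL = ED50 * (1/fraction - 1)^(1/tau).
#'
#' @param fit A `dose_response_fit`.
#' @param fraction Growth-rate fraction in (0.5, 1); default the fit's
#'   `noel_fraction` (0.98).
#' @return NOEL in J cm^-2 h^-1.
#' @export
noel <- function(fit, fraction = fit$noel_fraction) {
  if (!is.numeric(fraction) || fraction <= 0.5 || fraction >= 1)
    stop("`fraction` must lie in (0.5, 1)", call. = FALSE)
  fit$ed50 * (1 / fraction - 1)^(1 / fit$tau)
}

#' Dose rate at which the growth rate falls to a given fraction
#'
#' Inverse of [predict_gr()] on the normalized scale:
#' LD = ED50 * (1/fraction - 1)^(1/tau). `invert_dose(fit, 0.5)` is ED50;
#' `invert_dose(fit, 0.98)` is the NOEL.
#'
#' @inheritParams noel
#' @param gr_fraction Target growth-rate fraction of GR0, in (0, 1).
#' @return Dose rate in J cm^-2 h^-1.
#' @export
invert_dose <- function(fit, gr_fraction) {
  if (any(gr_fraction <= 0) || any(gr_fraction >= 1))
    stop("`gr_fraction` must lie in (0, 1)", call. = FALSE)
  fit$ed50 * (1 / gr_fraction - 1)^(1 / fit$tau)
}

#' Bootstrap confidence intervals for ED50, tau and the NOEL
#'
#' Case-resampling bootstrap of the LAD dose-effect fit: data points are
#' resampled with replacement (stratified by dose level so every replicate
#' retains all dose levels), the model is refit from the full-data estimate,
#' and percentile intervals are formed.
#'
#' @inheritParams fit_dose_response
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed Integer seed; replicates are deterministic given the seed.
#' @param level Confidence level, default 0.95.
#' @return The `dose_response_fit` with a `ci` matrix (rows ed50, tau, noel;
#'   columns lower, upper) and the replicate draws in `boot`.
#' @export
bootstrap_ci <- function(data, n_boot = 500, seed = 1, level = 0.95,
                         normalize = TRUE, noel_fraction = 0.98) {
  if (n_boot < 200) stop("`n_boot` must be at least 200", call. = FALSE)
  fit <- fit_dose_response(data, normalize = normalize,
                           noel_fraction = noel_fraction)
  d <- fit$data
  if (nrow(d) < 8L)
    stop("too few points to resample", call. = FALSE)
  start <- c(fit$gr0, log(fit$ed50), log(fit$tau))
  idx_by_dose <- split(seq_len(nrow(d)), d$dose)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("ed50", "tau", "noel")))
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_dose, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    db <- d[take, ]
    res <- fit_lad_once(db$dose, db$gr, start, maxit = 500)
    ed <- exp(res$par[2]); tau <- exp(res$par[3])
    reps[b, ] <- c(ed, tau, ed * (1 / noel_fraction - 1)^(1 / tau))
  }
  alpha <- (1 - level) / 2
  fit$ci <- t(apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                    names = FALSE))
  colnames(fit$ci) <- c("lower", "upper")
  fit$boot <- reps
  fit
}
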