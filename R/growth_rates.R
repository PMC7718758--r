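#' Cell-count time series of one culturing pad
#'
#' A pad is one culturing area of the microfluidic chip in which trapped cells
#' grow into a single-layer microcolony. Counts are total segmented cells in
#' the field of view at each time point. Pads where a colony reaches the
#' border of the field of view are flagged `excluded` (counts there
#' underestimate growth) and skipped by [aggregate_pads()].
#'
#' @param pad_id Pad identifier.
#' @param times Acquisition times in minutes, strictly increasing, starting
#'   at 0.
#' @param counts Cell counts (>= 1) at each time.
#' @param excluded Logical; `TRUE` if the colony reached the field-of-view
#'   border at any time.
#' @return An object of class `pad_counts`.
#' @export
pad_counts <- function(pad_id, times, counts, excluded = FALSE) {
  stopifnot(length(pad_id) == 1L)
  times <- as.numeric(times); counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop("`times` and `counts` must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("need at least two time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop(sprintf("pad %s: times must be strictly increasing", pad_id),
         call. = FALSE)
  if (times[1] != 0)
    stop(sprintf("pad %s: first time point must be 0", pad_id), call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop(sprintf("pad %s: counts must be finite and >= 1", pad_id),
         call. = FALSE)
  structure(list(pad_id = as.character(pad_id), times = times,
                 counts = counts, excluded = isTRUE(excluded)),
            class = "pad_counts")
}

#' @export
print.pad_counts <- function(x, ...) {
  cat(sprintf("Pad %s: %d time points over %g min, %g -> %g cells%s\n",
              x$pad_id, length(x$times), max(x$times), x$counts[1],
              x$counts[length(x$counts)],
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

new_growth_result <- function(gr_per_min, method, n_pads) {
  structure(list(
    growth_rate = gr_per_min,                       # doublings min^-1
    growth_rate_per_h = gr_per_min * 60,            # doublings h^-1
    doubling_time = if (gr_per_min > 0) 1 / gr_per_min else NA_real_,  # min
    method = method, n_pads = n_pads),
    class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf("Growth rate: %.4g doublings h-1 (doubling time %.4g min), %s, %d pad(s)\n",
              x$growth_rate_per_h, x$doubling_time, x$method, x$n_pads))
  invisible(x)
}

#' Average growth rate from first and last cell counts
#'
#' GR = log2(N(t_end)/N(0)) / t_end, in doublings per minute. Using only the
#' endpoints gives the average rate over the whole observation window, which
#' remains meaningful when growth slows part-way through (delayed onset of
#' photomorbidity); on purely exponential data it coincides with the
#' exponential fit.
#'
#' @param pad A [pad_counts()] object (not excluded).
#' @param t_end End of the observation window, minutes; must be an observed
#'   time point. Default: last observed time.
#' @return A `growth_result` with fields `growth_rate` (doublings min^-1),
#'   `growth_rate_per_h` and `doubling_time` (min).
#' @export
growth_rate_endpoint <- function(pad, t_end = max(pad$times)) {
  stopifnot(inherits(pad, "pad_counts"))
  if (pad$excluded)
    stop(sprintf("pad %s is excluded (colony reached field-of-view border)",
                 pad$pad_id), call. = FALSE)
  i0 <- match(0, pad$times); i1 <- match(t_end, pad$times)
  if (is.na(i1))
    stop(sprintf("pad %s: no count observed at t_end = %g min", pad$pad_id,
                 t_end), call. = FALSE)
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  gr <- log2(pad$counts[i1] / pad$counts[i0]) / t_end
  new_growth_result(gr, "endpoint", 1L)
}

#' Growth rate by exponential fit to all time points
#'
#' Fits N(t) = N(0) * 2^(GR * t) by least squares on log2 counts (linear
#' regression of log2 N on t), using every time point.
#'
#' @inheritParams growth_rate_endpoint
#' @return A `growth_result`.
#' @export
growth_rate_expfit <- function(pad) {
  stopifnot(inherits(pad, "pad_counts"))
  if (pad$excluded)
    stop(sprintf("pad %s is excluded", pad$pad_id), call. = FALSE)
  if (length(pad$times) < 3L)
    stop("exponential fit needs at least 3 time points", call. = FALSE)
  fit <- stats::lm(log2(counts) ~ times,
                   data = list(times = pad$times, counts = pad$counts))
  new_growth_result(unname(stats::coef(fit)[2]), "expfit", 1L)
}

#' Pool pads of one condition and compute the growth rate
#'
#' Sums the cell counts of all non-excluded pads at each time point (the pads
#' of a condition are summed into one population trajectory before the growth
#' rate is computed) and applies the chosen growth-rate method.
#'
#' @param pads List of [pad_counts()] objects sharing the same time grid.
#' @param method `"endpoint"` (default) or `"expfit"`.
#' @param t_end Passed to [growth_rate_endpoint()].
#' @return A `growth_result`; `n_pads` records how many pads were pooled.
#' @export
aggregate_pads <- function(pads, method = c("endpoint", "expfit"),
                           t_end = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(pads), all(vapply(pads, inherits, TRUE, "pad_counts")))
  keep <- Filter(function(p) !p$excluded, pads)
  if (length(keep) == 0L)
    stop("all pads are excluded; cannot compute a growth rate", call. = FALSE)
  times <- keep[[1]]$times
  for (p in keep) {
    if (length(p$times) != length(times) || any(p$times != times))
      stop("pads must share a common time grid to be summed", call. = FALSE)
  }
  total <- Reduce(`+`, lapply(keep, `[[`, "counts"))
  pooled <- pad_counts("pooled", times, total)
  res <- switch(method,
    endpoint = growth_rate_endpoint(pooled,
                                    t_end = if (is.null(t_end)) max(times) else t_end),
    expfit = growth_rate_expfit(pooled))
  res$n_pads <- length(keep)
  res
}

#' Normalize a growth rate to the unilluminated control
#'
#' @param treated,control `growth_result` objects (or bare growth rates in
#'   the same units).
#' @return Fraction treated/control; 1 means no effect.
#' @export
normalize_to_control <- function(treated, control) {
  gr_t <- if (inherits(treated, "growth_result")) treated$growth_rate else treated
  gr_c <- if (inherits(control, "growth_result")) control$growth_rate else control
  if (!is.numeric(gr_c) || gr_c <= 0)
    stop("control growth rate must be positive", call. = FALSE)
  gr_t / gr_c
}

#' Residuals of an early-window exponential fit
#'
#' Fits the exponential growth model to the counts observed within the first
#' `window` minutes only, then returns observed minus predicted counts over
#' the whole time course. Under delayed-onset photomorbidity the colony grows
#' at the unstressed rate at first, so residuals are near zero early and turn
#' increasingly negative once growth retardation sets in — a diagnostic for
#' the onset time of morbidity.
#'
#' @inheritParams growth_rate_endpoint
#' @param window Fit window in minutes (default 180, i.e. the first 3 h).
#' @return A data frame with columns `time_min`, `observed`, `predicted`,
#'   `residual`.
#' @export
early_window_residuals <- function(pad, window = 180) {
  stopifnot(inherits(pad, "pad_counts"))
  if (window > max(pad$times))
    stop("fit window extends beyond the observed time course", call. = FALSE)
  early <- pad$times <= window
  if (sum(early) < 3L)
    stop("need at least 3 time points inside the fit window", call. = FALSE)
  fit <- stats::lm(log2(counts) ~ times,
                   data = list(times = pad$times[early],
                               counts = pad$counts[early]))
  pred <- 2^(stats::coef(fit)[1] + stats::coef(fit)[2] * pad$times)
  data.frame(time_min = pad$times, observed = pad$counts,
             predicted = unname(pred),
             residual = pad$counts - unname(pred))
}
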