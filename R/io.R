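#' Read pad cell-count time series from CSV
#'
#' Expected schema: columns `pad_id,time_min,cell_count,excluded`. Each pad's
#' rows must have strictly increasing times starting at 0 and counts >= 1;
#' violations are reported with the offending pad named.
#'
#' @param path Path to a CSV file.
#' @return List of [pad_counts()] objects, one per pad.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pad_id", "time_min", "cell_count", "excluded")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("counts CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("counts CSV has no data rows", call. = FALSE)
  lapply(split(df, df$pad_id), function(p) {
    p <- p[order(p$time_min), ]
    pad_counts(p$pad_id[1], p$time_min, p$cell_count,
               excluded = any(as.logical(p$excluded)))
  })
}

#' Write pad cell-count time series to CSV
#'
#' Inverse of [read_counts_csv()]; `write` then `read` round-trips exactly.
#'
#' @param pads List of [pad_counts()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(pads, path) {
  rows <- do.call(rbind, lapply(pads, function(p)
    data.frame(pad_id = p$pad_id, time_min = p$times, cell_count = p$counts,
               excluded = p$excluded)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read fluorescence intensity summaries from CSV
#'
#' Expected schema:
#' `dose_J_cm2,mean_signal,mean_background,sd_signal,sd_background,n_cells`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with a `dose` column, ready for
#'   [fit_channel_calibration()].
#' @export
read_intensity_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_J_cm2", "mean_signal", "mean_background", "sd_signal",
            "sd_background", "n_cells")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("intensity CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("intensity CSV has no data rows", call. = FALSE)
  if (any(df$sd_signal < 0) || any(df$sd_background < 0))
    stop("intensity CSV contains negative standard deviations", call. = FALSE)
  if (any(df$dose_J_cm2 < 0))
    stop("intensity CSV contains negative doses", call. = FALSE)
  names(df)[names(df) == "dose_J_cm2"] <- "dose"
  df
}

#' Write fluorescence intensity summaries to CSV
#'
#' @param measurements Data frame as returned by
#'   [simulate_intensity_measurements()] or [read_intensity_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_csv <- function(measurements, path) {
  m <- as.data.frame(measurements)
  if ("dose" %in% names(m)) names(m)[names(m) == "dose"] <- "dose_J_cm2"
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response table from CSV
#'
#' Expected schema: `dose_J_cm2_h,growth_rate`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `dose`, `gr`, ready for
#'   [fit_dose_response()].
#' @export
read_dose_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_J_cm2_h", "growth_rate")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("dose-response CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  data.frame(dose = df$dose_J_cm2_h, gr = df$growth_rate)
}

#' Assemble a per-fluorophore summary row
#'
#' Collects, for one fluorophore/channel, the quantities a practitioner needs
#' to choose reporters: relative brightness, background accumulation rate,
#' the light dose and expected growth-rate fraction required to image each
#' abundance tier at the target SNR, and the 50%-bleach dose.
#'
#' @param name Fluorophore name.
#' @param cal Its `channel_calibration`.
#' @param cal_ref Reference (GFP) calibration for relative brightness, or
#'   `NULL`.
#' @param morbidity_fit `dose_response_fit` of the excitation band.
#' @param bleach_fit Optional `bleach_fit`.
#' @param ratios Named abundance ratios (default [abundance_ratios()]).
#' @param target_snr,interval_min As in [gr_at_snr_target()].
#' @return One-row data frame.
#' @export
fluorophore_summary <- function(name, cal, cal_ref = NULL, morbidity_fit,
                                bleach_fit = NULL,
                                ratios = abundance_ratios(),
                                target_snr = 4, interval_min = 5) {
  row <- data.frame(fluorophore = name, stringsAsFactors = FALSE)
  row$relative_brightness <- if (!is.null(cal_ref))
    relative_brightness(cal, cal_ref) else NA_real_
  row$bg_rate <- cal$bg_slope
  for (tier in names(ratios)) {
    res <- tryCatch(
      gr_at_snr_target(cal, ratios[[tier]], target_snr, morbidity_fit,
                       interval_min),
      infeasible_error = function(e)
        list(dose_rate = NA_real_, gr_fraction = NA_real_))
    row[[paste0("ld_", tier)]] <- res$dose_rate
    row[[paste0("gr_", tier)]] <- 100 * res$gr_fraction
  }
  ld50 <- if (!is.null(bleach_fit)) ld_bleach50(bleach_fit) else NA_real_
  row$ld_bleach50 <- ld50
  row$bleach_safe <- if (is.finite(ld50))
    bleach_safe_at_noel(ld50, noel(morbidity_fit)) else NA
  row
}

#' Write a fluorophore performance report
#'
#' Writes two CSV files: `<path>` with values rounded to 4 significant
#' figures for reading, and `<path stem>_full.csv` with full precision for
#' downstream machine use. An empty summary produces a valid header-only
#' report.
#'
#' @param summary Data frame of [fluorophore_summary()] rows (possibly
#'   0 rows).
#' @param path Output path of the human-readable report.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_report <- function(summary, path) {
  s <- as.data.frame(summary)
  rounded <- s
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], signif, digits = 4)
  utils::write.csv(rounded, path, row.names = FALSE)
  full <- sub("(\\.[^.]+)?$", "_full.csv", path)
  if (identical(full, path)) full <- paste0(path, "_full.csv")
  utils::write.csv(s, full, row.names = FALSE)
  invisible(c(path, full))
}
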