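#' Fraction of physiologically valid intervals
#'
#' @param ibi a [build_ibi()] result.
#' @return fraction in `[0, 1]` of intervals whose validity mask is TRUE.
#' @export
valid_peak_fraction <- function(ibi) {
  if (!length(ibi$valid)) stop("empty IBI series", call. = FALSE)
  mean(ibi$valid)
}

#' Beat-template signal-to-noise ratio
#'
#' Estimates how much of the waveform's cardiac-band power is beat-locked.
#' The waveform is band-passed to the cardiac band (0.5-10 Hz, zero
#' phase), a window of half the median inter-beat interval on each side is
#' cut around every detected beat (so the windows tile the full cycle),
#' and the beat template is the ensemble mean of these windows. Signal
#' power is the template's mean square; each beat's noise power is the
#' mean square of its residual from the template. The reported value is
#' the mean over beats of `10 log10(P_signal / P_noise_beat)`, clipped to
#' `[-60, 60]` dB. Because beat windows are aligned at the detected peak,
#' the estimate is indifferent to rhythm irregularity — a clean
#' fibrillation recording scores as high as a clean sinus one — while an
#' in-band white-noise contamination of power equal to the in-band signal
#' power reads close to 0 dB.
#'
#' @param rec a [recording()] (raw or filtered; affine amplitude scaling
#'   does not change the estimate).
#' @param peaks a [peak_series()] with at least 4 peaks.
#' @return mean SNR in dB.
#' @export
estimate_snr_db <- function(rec, peaks) {
  if (length(peaks$indices) < 4) stop("need at least 4 peaks", call. = FALSE)
  fs <- rec$fs
  hi <- min(10, 0.45 * fs)
  bf <- signal::butter(2, c(0.5, hi) / (fs / 2), type = "pass")
  z <- signal::filtfilt(bf, rec$samples)
  idx <- peaks$indices
  w <- max(1L, round(0.5 * median(diff(idx))))
  idx <- idx[idx - w >= 1 & idx + w <= length(z)]
  if (length(idx) < 3) return(-60)
  M <- vapply(idx, function(i) z[(i - w):(i + w)], numeric(2L * w + 1L))
  template <- rowMeans(M)
  p_signal <- mean(template^2)
  p_noise <- colMeans((M - template)^2)
  if (p_signal <= 0) return(-60)
  mean(pmin(60, pmax(-60, 10 * log10(p_signal / p_noise))))
}

#' Two-step signal-quality gate
#'
#' Screens a segment before any rhythm prediction: (1) at least
#' `min_valid_fraction` (default 75%) of the inter-beat intervals must lie
#' within physiological bounds, and (2) the mean spectral SNR must exceed
#' `min_snr_db` (default 5 dB). Runs the full conditioning + beat
#' detection chain internally and always returns a report rather than
#' erroring, so callers can log why a segment was rejected.
#'
#' @param rec a raw [recording()].
#' @param cfg an [afib_config()].
#' @return object of class `quality_report`: `valid_peak_fraction`,
#'   `mean_snr_db`, `passed`, `reasons` (character, empty when passed).
#' @export
quality_gate <- function(rec, cfg = afib_config()) {
  report <- function(frac, snr, reasons) {
    structure(list(valid_peak_fraction = frac, mean_snr_db = snr,
                   passed = length(reasons) == 0L, reasons = reasons),
              class = "quality_report")
  }
  cond <- tryCatch(preprocess_record(rec, cfg), error = function(e) NULL)
  if (is.null(cond)) return(report(0, -Inf, "preprocessing_failed"))
  peaks <- correct_double_peaks(detect_peaks(cond, cfg), cfg$min_sep_ms)
  if (length(peaks$indices) < 2) return(report(0, -Inf, "too_few_peaks"))
  ibi <- build_ibi(peaks, length(cond$samples), cfg$min_ibi_ms, cfg$max_ibi_ms)
  frac <- valid_peak_fraction(ibi)
  snr <- tryCatch(estimate_snr_db(bandpass(smooth_sg(rec, cfg), cfg), peaks),
                  error = function(e) -Inf)
  reasons <- character(0)
  if (frac < cfg$min_valid_fraction) reasons <- c(reasons, "valid_peak_fraction")
  if (!(snr > cfg$min_snr_db)) reasons <- c(reasons, "snr")
  report(frac, snr, reasons)
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s: valid fraction %.2f, SNR %.1f dB%s\n",
              if (x$passed) "PASS" else "FAIL", x$valid_peak_fraction,
              x$mean_snr_db,
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Serialize a quality report to JSON
#' @param report a [quality_gate()] result.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to file.
#' @export
quality_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
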