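#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing; the default (order 4, 19-sample
#' window) suppresses high-frequency noise while leaving QRS/systolic peak
#' morphology — anything locally polynomial up to order 4 — untouched.
#'
#' @param rec a [recording()].
#' @param cfg an [afib_config()] supplying `sg_order` and `sg_frames`.
#' @return smoothed [recording()], same length and fs.
#' @export
smooth_sg <- function(rec, cfg = afib_config()) {
  if (length(rec$samples) < cfg$sg_frames) {
    stop("record shorter than the smoothing window", call. = FALSE)
  }
  y <- signal::sgolayfilt(rec$samples, p = cfg$sg_order, n = cfg$sg_frames)
  recording(y, rec$fs, rec$modality, rec$subject_id, rec$record_id)
}

#' Zero-phase Butterworth band-pass
#'
#' Second-order Butterworth, 0.5-20 Hz by default, applied forward-backward
#' (`filtfilt`) so that beat positions are not shifted by filter group
#' delay; interval accuracy dominates everything downstream. At low
#' sampling rates (50 Hz PPG) the upper cutoff is clamped to `0.4 * fs` to
#' stay under Nyquist.
#'
#' @inheritParams smooth_sg
#' @return filtered [recording()], same length.
#' @export
bandpass <- function(rec, cfg = afib_config()) {
  nyq <- rec$fs / 2
  hi <- min(cfg$bp_high, 0.4 * rec$fs)
  if (cfg$bp_low >= nyq) stop("low cutoff at or above Nyquist", call. = FALSE)
  bf <- signal::butter(cfg$bp_order, c(cfg$bp_low, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, rec$samples)
  recording(y, rec$fs, rec$modality, rec$subject_id, rec$record_id)
}

#' Scaled min-max normalization
#'
#' Maps the waveform affinely onto `[0, scale]` (default scale 10). A
#' constant signal has zero dynamic range and is rejected — the quality
#' gate should have discarded it.
#'
#' @param rec a [recording()].
#' @param scale upper bound of the output range.
#' @return normalized [recording()] spanning exactly `[0, scale]`.
#' @export
minmax_normalize <- function(rec, scale = 10) {
  stopifnot(scale > 0)
  rng <- range(rec$samples)
  if (rng[1] == rng[2]) stop("zero dynamic range", call. = FALSE)
  y <- scale * (rec$samples - rng[1]) / (rng[2] - rng[1])
  recording(y, rec$fs, rec$modality, rec$subject_id, rec$record_id)
}

#' Full conditioning chain
#'
#' Smooth, band-pass, then min-max normalize, in that order.
#'
#' @inheritParams smooth_sg
#' @return conditioned [recording()] spanning `[0, norm_scale]`.
#' @export
preprocess_record <- function(rec, cfg = afib_config()) {
  minmax_normalize(bandpass(smooth_sg(rec, cfg), cfg), cfg$norm_scale)
}
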