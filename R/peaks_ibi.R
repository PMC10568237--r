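#' Detected beat positions
#'
#' @param indices strictly increasing 1-based sample positions.
#' @param fs sampling rate in Hz.
#' @param amplitude waveform amplitude at each peak (used by
#'   [correct_double_peaks()]).
#' @return object of class `peak_series`.
#' @export
peak_series <- function(indices, fs, amplitude = rep(NA_real_, length(indices))) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  structure(list(indices = indices, fs = fs, amplitude = as.numeric(amplitude)),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Adaptive beat detection
#'
#' Modality-agnostic detector for ECG R-waves and PPG systolic peaks on a
#' conditioned waveform (see [preprocess_record()]): local maxima above an
#' adaptive threshold — half the rolling maximum amplitude over 2-s blocks
#' (every block this long contains at least one beat at physiological
#' rates, and the block maximum tracks the local beat amplitude for sparse
#' R-spikes and broad systolic pulses alike) — thinned to a minimum
#' inter-peak (refractory) distance by keeping the larger peak. Fewer than
#' 2 detected peaks yields an empty series, which callers treat as an
#' unusable segment.
#'
#' @param rec a conditioned [recording()].
#' @param cfg an [afib_config()] supplying `refractory_s`.
#' @return a [peak_series()].
#' @export
detect_peaks <- function(rec, cfg = afib_config()) {
  x <- rec$samples
  n <- length(x)
  fs <- rec$fs
  block <- max(2L, round(2 * fs))
  thr <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    thr[s:e] <- 0.5 * max(x[s:e])
  }
  # beat-free blocks (e.g. record edges) would otherwise threshold on noise
  thr <- pmax(thr, 0.25 * max(x))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] > thr[cand]]
  if (!length(cand)) return(peak_series(integer(0), fs, numeric(0)))
  mind <- max(1L, round(cfg$refractory_s * fs))
  ord <- cand[order(-x[cand], cand)]
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) >= mind)) taken <- c(taken, i)
  }
  idx <- sort(taken)
  if (length(idx) < 2) return(peak_series(integer(0), fs, numeric(0)))
  peak_series(idx, fs, x[idx])
}

#' Double-peak correction
#'
#' Notched R-waves or dicrotic PPG bumps can produce two detections for one
#' beat. Wherever two peaks lie closer than `min_sep_ms`, the one with the
#' larger amplitude is kept; the rule is iterated until no violation
#' remains (idempotent).
#'
#' @param peaks a [peak_series()] carrying amplitudes.
#' @param min_sep_ms minimum separation in milliseconds (default 250).
#' @return a [peak_series()].
#' @export
correct_double_peaks <- function(peaks, min_sep_ms = 250) {
  idx <- peaks$indices
  amp <- peaks$amplitude
  min_gap <- min_sep_ms * peaks$fs / 1000
  repeat {
    if (length(idx) < 2) break
    gaps <- diff(idx)
    v <- which(gaps < min_gap)
    if (!length(v)) break
    i <- v[1]
    drop <- if (amp[i] >= amp[i + 1]) i + 1L else i
    idx <- idx[-drop]
    amp <- amp[-drop]
  }
  peak_series(idx, peaks$fs, amp)
}

#' Build the validated inter-beat-interval series
#'
#' Converts consecutive peak gaps into intervals in milliseconds, marks
#' each interval valid when it lies within physiological bounds
#' (`min_ibi_ms` to `max_ibi_ms`, default 270-1500 ms), and expands the
#' series to the full record length by sample-and-hold so every waveform
#' sample carries the interval of the gap containing it (edge samples carry
#' the nearest interval). The masked expansion zeroes invalid intervals.
#'
#' @param peaks a [peak_series()] with at least 2 peaks.
#' @param record_len length of the parent record in samples.
#' @param min_ibi_ms,max_ibi_ms validity bounds in milliseconds.
#' @return object of class `ibi_series` with fields `intervals_ms`, `valid`,
#'   `expanded`, `masked_expanded`, `peak_indices`, `fs`, `record_len`,
#'   `min_ibi_ms`, `max_ibi_ms`.
#' @export
build_ibi <- function(peaks, record_len, min_ibi_ms = 270, max_ibi_ms = 1500) {
  idx <- peaks$indices
  if (length(idx) < 2) stop("need at least 2 peaks", call. = FALSE)
  if (max(idx) > record_len) stop("peaks beyond record length", call. = FALSE)
  intervals <- diff(idx) * 1000 / peaks$fs
  valid <- intervals >= min_ibi_ms & intervals <= max_ibi_ms
  # sample t in [idx[k], idx[k+1]) holds interval k; edges hold the nearest
  gap_of <- findInterval(seq_len(record_len), idx)
  gap_of[gap_of < 1L] <- 1L
  gap_of[gap_of > length(intervals)] <- length(intervals)
  expanded <- intervals[gap_of]
  masked <- ifelse(valid, intervals, 0)[gap_of]
  structure(
    list(intervals_ms = intervals, valid = valid, expanded = expanded,
         masked_expanded = masked, peak_indices = idx, fs = peaks$fs,
         record_len = as.integer(record_len),
         min_ibi_ms = min_ibi_ms, max_ibi_ms = max_ibi_ms),
    class = "ibi_series"
  )
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals (%d valid), bounds [%g, %g] ms\n",
              length(x$intervals_ms), sum(x$valid), x$min_ibi_ms,
              x$max_ibi_ms))
  invisible(x)
}

#' Find reliable analysis frames
#'
#' Slides a window over the record and keeps every frame in which no
#' covered interval is invalidated by the physiological-bounds mask and at
#' least 2 peaks fall inside — i.e. the stretches whose beat timing can be
#' trusted. An interval is "covered" when its peak-to-peak span intersects
#' the frame.
#'
#' @param ibi an [build_ibi()] result.
#' @param window_s frame length in seconds.
#' @param stride_s frame step in seconds.
#' @return list of `reliable_frame` objects (`start_sample`, `end_sample`
#'   half-open, `peak_indices`).
#' @export
find_reliable_frames <- function(ibi, window_s = 8, stride_s = 2) {
  stopifnot(window_s > 0, stride_s > 0)
  wn <- round(window_s * ibi$fs)
  step <- round(stride_s * ibi$fs)
  n <- ibi$record_len
  if (n < wn) return(list())
  idx <- ibi$peak_indices
  gap_start <- idx[-length(idx)]
  gap_end <- idx[-1]
  out <- list()
  for (s in seq(1L, n - wn + 1L, by = step)) {
    e <- s + wn # half-open [s, e)
    covered <- which(gap_start < e & gap_end > s)
    if (length(covered) && !all(ibi$valid[covered])) next
    inside <- idx[idx >= s & idx < e]
    if (length(inside) < 2) next
    out[[length(out) + 1L]] <- structure(
      list(start_sample = s, end_sample = e, peak_indices = inside),
      class = "reliable_frame"
    )
  }
  out
}

#' Export the interval series as a data frame
#' @param ibi an [build_ibi()] result.
#' @return data.frame with `sample_index` (of the gap start), `interval_ms`,
#'   `valid`.
#' @export
ibi_as_data_frame <- function(ibi) {
  data.frame(sample_index = ibi$peak_indices[-length(ibi$peak_indices)],
             interval_ms = ibi$intervals_ms, valid = ibi$valid)
}
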