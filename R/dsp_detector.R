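# Training-free AFIB detector: rate of abnormal first-derivative spikes
# of the inter-beat-interval sequence, averaged over sliding frames.

#' Per-frame abnormal-spike statistics
#'
#' The first derivative of a frame's IBI sequence is the successive
#' difference of its per-gap interval values in ms; a sudden rhythm change
#' shows up as a spike. A difference whose magnitude exceeds
#' `spike_threshold_ms` (default 50 ms) counts as abnormal, and the frame
#' statistic is the ratio of abnormal spikes to the number of peaks in the
#' frame. The derivative is taken on the per-gap sequence, not the
#' sample-expanded signal, so the ms threshold is dimensionally meaningful
#' and independent of the sampling rate.
#'
#' @param frame a `reliable_frame` from [find_reliable_frames()] with at
#'   least 3 peaks.
#' @param ibi the parent [build_ibi()] series.
#' @param spike_threshold_ms abnormal-change threshold in ms.
#' @return list of class `dsp_frame_stat`: `has_abnormal`,
#'   `abnormal_ratio`, `n_peaks`, `n_spikes`.
#' @export
frame_spike_stats <- function(frame, ibi, spike_threshold_ms = 50) {
  n_peaks <- length(frame$peak_indices)
  if (n_peaks < 3) stop("frame needs at least 3 peaks", call. = FALSE)
  pos <- match(frame$peak_indices, ibi$peak_indices)
  intervals <- ibi$intervals_ms[pos[-length(pos)]]
  d <- diff(intervals)
  n_spikes <- sum(abs(d) > spike_threshold_ms)
  structure(
    list(has_abnormal = n_spikes > 0, abnormal_ratio = n_spikes / n_peaks,
         n_peaks = n_peaks, n_spikes = n_spikes),
    class = "dsp_frame_stat"
  )
}

#' Classify a recording with the signal-processing method
#'
#' Runs the full chain — conditioning, beat detection, double-peak
#' correction, IBI validation, reliable-frame search (8-s window, 2-s
#' stride by default) — then computes the abnormal-spike ratio of every
#' frame with at least 3 peaks and labels the recording AFIB when the
#' mean ratio over frames exceeds `decision_threshold`. Frames with fewer
#' than 3 peaks are skipped rather than counted as zero so they do not
#' dilute the mean. A recording yielding no usable frame is
#' "UNCLASSIFIABLE", distinct from either rhythm label.
#'
#' @param rec a raw [recording()].
#' @param cfg an [afib_config()].
#' @return object of class `dsp_decision`: `label` ("AFIB", "NSR" or
#'   "UNCLASSIFIABLE"), `mean_ratio`, `frame_stats` (per-frame audit
#'   trail), `spike_threshold_ms`, `decision_threshold`.
#' @export
classify_dsp <- function(rec, cfg = afib_config()) {
  decision <- function(label, mean_ratio, stats) {
    structure(list(label = label, mean_ratio = mean_ratio,
                   frame_stats = stats,
                   spike_threshold_ms = cfg$spike_threshold_ms,
                   decision_threshold = cfg$decision_threshold),
              class = "dsp_decision")
  }
  cond <- tryCatch(preprocess_record(rec, cfg), error = function(e) NULL)
  if (is.null(cond)) return(decision("UNCLASSIFIABLE", NA_real_, list()))
  peaks <- correct_double_peaks(detect_peaks(cond, cfg), cfg$min_sep_ms)
  if (length(peaks$indices) < 3) {
    return(decision("UNCLASSIFIABLE", NA_real_, list()))
  }
  ibi <- build_ibi(peaks, length(cond$samples), cfg$min_ibi_ms, cfg$max_ibi_ms)
  frames <- find_reliable_frames(ibi, cfg$dsp_window_s, cfg$dsp_stride_s)
  frames <- Filter(function(f) length(f$peak_indices) >= 3, frames)
  if (!length(frames)) return(decision("UNCLASSIFIABLE", NA_real_, list()))
  stats <- lapply(frames, frame_spike_stats, ibi = ibi,
                  spike_threshold_ms = cfg$spike_threshold_ms)
  mean_ratio <- mean(vapply(stats, `[[`, numeric(1), "abnormal_ratio"))
  label <- if (mean_ratio > cfg$decision_threshold) "AFIB" else "NSR"
  decision(label, mean_ratio, stats)
}

#' @export
print.dsp_decision <- function(x, ...) {
  cat(sprintf("<dsp_decision> %s (mean abnormal ratio %.3f over %d frames, spike > %g ms, cutoff %g)\n",
              x$label, x$mean_ratio, length(x$frame_stats),
              x$spike_threshold_ms, x$decision_threshold))
  invisible(x)
}

#' Calibrate the decision threshold on labelled data
#'
#' The mean-ratio cutoff is a free parameter of the signal-processing
#' method. Given labelled recordings, this sweeps every candidate cutoff
#' between the observed mean ratios and reports the Youden-optimal point
#' (maximizing sensitivity + specificity - 1, with AFIB positive).
#'
#' @param mean_ratios numeric vector of per-recording mean abnormal
#'   ratios (e.g. from [classify_dsp()] decisions).
#' @param labels true labels, "NSR"/"AFIB".
#' @return list: `threshold` (Youden-optimal cutoff), `youden_j`,
#'   `sweep` (data.frame of threshold, sensitivity, specificity, j).
#' @export
calibrate_dsp_threshold <- function(mean_ratios, labels) {
  stopifnot(length(mean_ratios) == length(labels))
  keep <- !is.na(mean_ratios)
  mean_ratios <- mean_ratios[keep]
  labels <- labels[keep]
  if (!all(c("NSR", "AFIB") %in% labels)) {
    stop("need both classes to calibrate", call. = FALSE)
  }
  cand <- sort(unique(mean_ratios))
  cand <- c(cand[1] - 1e-9, (cand[-1] + cand[-length(cand)]) / 2)
  sweep <- do.call(rbind, lapply(cand, function(th) {
    pred_afib <- mean_ratios > th
    sens <- mean(pred_afib[labels == "AFIB"])
    spec <- mean(!pred_afib[labels == "NSR"])
    data.frame(threshold = th, sensitivity = sens, specificity = spec,
               j = sens + spec - 1)
  }))
  best <- which.max(sweep$j)
  list(threshold = sweep$threshold[best], youden_j = sweep$j[best],
       sweep = sweep)
}
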