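#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one flat list with the
#' published defaults. Unknown keys are rejected so typos cannot silently
#' fall back to defaults. A configuration can also be loaded from a YAML
#' file whose keys are a subset of these.
#'
#' @param ... name = value overrides of the defaults below.
#' @param file optional path to a YAML file of overrides, applied before
#'   `...`.
#'
#' @details Defaults:
#' \describe{
#'   \item{sg_order, sg_frames}{Savitzky-Golay smoother: order 4, 19-sample
#'     window.}
#'   \item{bp_order, bp_low, bp_high}{Butterworth band-pass: order 2,
#'     0.5-20 Hz, applied forward-backward (zero phase).}
#'   \item{norm_scale}{min-max normalization scale, 10.}
#'   \item{min_ibi_ms, max_ibi_ms}{physiological interval bounds for the
#'     validity mask, 270-1500 ms (about 40-220 bpm).}
#'   \item{refractory_s}{beat-detector minimum inter-peak distance, 0.27 s.}
#'   \item{min_sep_ms}{double-peak correction separation, 250 ms.}
#'   \item{dsp_window_s, dsp_stride_s}{DSP frames: 8 s window, 2 s stride.}
#'   \item{spike_threshold_ms}{abnormal first-derivative spike threshold,
#'     50 ms.}
#'   \item{decision_threshold}{mean abnormal-ratio cutoff for AFIB, 0.15.}
#'   \item{hrv_window_s, hrv_stride_s}{HRV frames: 15 s window, 2 s stride.}
#'   \item{hrmad_on}{"nn" (mean absolute deviation of the NN series, ms;
#'     makes MCVNN dimensionless) or "bpm" (of the 60000/NN heart-rate
#'     series).}
#'   \item{hti_bin_ms}{triangular-index histogram bin width, 1000/128 ms.}
#'   \item{min_valid_fraction, min_snr_db}{quality gate: at least 75% valid
#'     intervals and mean SNR above 5 dB.}
#'   \item{split_fraction}{subject-wise training fraction, 0.6.}
#'   \item{vote_tie}{label assigned on a 50/50 frame vote, "AFIB"
#'     (sensitivity-favouring).}
#'   \item{rf_ntree, svm_cost, knn_k}{learner hyperparameters.}
#' }
#'
#' @return a named list of class `afib_config`.
#' @export
#' @examples
#' cfg <- afib_config(spike_threshold_ms = 40)
#' cfg$spike_threshold_ms
afib_config <- function(..., file = NULL) {
  defaults <- list(
    sg_order = 4L, sg_frames = 19L,
    bp_order = 2L, bp_low = 0.5, bp_high = 20,
    norm_scale = 10,
    min_ibi_ms = 270, max_ibi_ms = 1500,
    refractory_s = 0.27,
    min_sep_ms = 250,
    dsp_window_s = 8, dsp_stride_s = 2,
    spike_threshold_ms = 50,
    decision_threshold = 0.15,
    hrv_window_s = 15, hrv_stride_s = 2,
    hrmad_on = "nn",
    hti_bin_ms = 1000 / 128,
    min_valid_fraction = 0.75,
    min_snr_db = 5,
    split_fraction = 0.6,
    vote_tie = "AFIB",
    rf_ntree = 300L,
    svm_cost = 1,
    knn_k = 15L
  )
  overrides <- list(...)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    overrides <- modifyList(from_file, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, overrides)
  stopifnot(cfg$bp_low > 0, cfg$bp_low < cfg$bp_high,
            cfg$sg_frames %% 2 == 1, cfg$sg_frames > cfg$sg_order,
            cfg$norm_scale > 0, cfg$min_ibi_ms < cfg$max_ibi_ms,
            cfg$hrmad_on %in% c("nn", "bpm"),
            cfg$vote_tie %in% c("AFIB", "NSR"))
  structure(cfg, class = "afib_config")
}

#' @export
print.afib_config <- function(x, ...) {
  cat("<afib_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
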