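# The seven per-frame heart-rate-variability features driving the ML
# detector. NN denotes the valid (artifact-filtered) intervals in ms.

#' Names of the seven HRV features, in the frozen model order
#' @return character vector.
#' @export
hrv_feature_names <- function() {
  c("hrmad", "rmssd", "iqrnn", "mcvnn", "cvnn", "cvsd", "hti")
}

#' Compute the seven HRV features for one frame
#'
#' Over the frame's NN intervals (valid intervals, ms):
#' \describe{
#'   \item{hrmad}{mean absolute deviation; by default of the NN series in
#'     ms, optionally (`hrmad_on = "bpm"`) of the instantaneous heart-rate
#'     series `60000 / NN`.}
#'   \item{rmssd}{root mean square of successive NN differences, ms.}
#'   \item{iqrnn}{inter-quartile range of NN, ms (linear-interpolation
#'     quartiles, R type 7).}
#'   \item{mcvnn}{`hrmad / median(NN)`; dimensionless with the default
#'     ms-based hrmad.}
#'   \item{cvnn}{`sd(NN) / mean(NN)` (sample SD).}
#'   \item{cvsd}{`rmssd / mean(NN)`.}
#'   \item{hti}{triangular index: NN count divided by the modal bin count
#'     of the NN histogram at a fixed 1000/128 ms bin width.}
#' }
#'
#' @param frame a `reliable_frame` from [find_reliable_frames()].
#' @param ibi the parent [build_ibi()] series.
#' @param cfg an [afib_config()] (`hrmad_on`, `hti_bin_ms`).
#' @return one-row `data.frame` with the seven feature columns.
#' @export
compute_features <- function(frame, ibi, cfg = afib_config()) {
  pos <- match(frame$peak_indices, ibi$peak_indices)
  gaps <- pos[-length(pos)]
  nn <- ibi$intervals_ms[gaps][ibi$valid[gaps]]
  if (length(nn) < 5) stop("frame needs at least 5 valid intervals",
                           call. = FALSE)
  d <- diff(nn)
  rmssd <- sqrt(mean(d^2))
  hrmad <- if (cfg$hrmad_on == "bpm") {
    hr <- 60000 / nn
    mean(abs(hr - mean(hr)))
  } else {
    mean(abs(nn - mean(nn)))
  }
  counts <- tabulate(floor(nn / cfg$hti_bin_ms) + 1L)
  data.frame(
    hrmad = hrmad,
    rmssd = rmssd,
    iqrnn = unname(diff(quantile(nn, c(0.25, 0.75), type = 7))),
    mcvnn = hrmad / median(nn),
    cvnn = sd(nn) / mean(nn),
    cvsd = rmssd / mean(nn),
    hti = length(nn) / max(counts)
  )
}

#' Build the frame-level HRV feature table
#'
#' Runs each single-rhythm block through conditioning, beat detection and
#' IBI validation, slides the HRV analysis window (15 s, 2-s stride by
#' default) over it, and emits one feature row per reliable frame with at
#' least 5 valid intervals. Block label and subject are propagated so the
#' table is ready for subject-wise splitting; rows are ordered by
#' (subject, block, frame start). Blocks failing the optional quality
#' gate, or yielding no usable frames, contribute no rows.
#'
#' @param blocks list of `rhythm_block` objects (see [split_by_rhythm()],
#'   [make_cohort()]).
#' @param cfg an [afib_config()].
#' @param gate apply [quality_gate()] per block first (recommended for
#'   PPG).
#' @return `data.frame` with columns `hrmad, rmssd, iqrnn, mcvnn, cvnn,
#'   cvsd, hti, label, subject_id, block_id, frame_start_s`.
#' @export
extract_dataset <- function(blocks, cfg = afib_config(), gate = FALSE) {
  rows <- lapply(blocks, function(blk) {
    rec <- blk$recording
    if (gate && !quality_gate(rec, cfg)$passed) return(NULL)
    cond <- tryCatch(preprocess_record(rec, cfg), error = function(e) NULL)
    if (is.null(cond)) return(NULL)
    peaks <- correct_double_peaks(detect_peaks(cond, cfg), cfg$min_sep_ms)
    if (length(peaks$indices) < 2) return(NULL)
    ibi <- build_ibi(peaks, length(cond$samples), cfg$min_ibi_ms,
                     cfg$max_ibi_ms)
    frames <- find_reliable_frames(ibi, cfg$hrv_window_s, cfg$hrv_stride_s)
    feats <- lapply(frames, function(f) {
      row <- tryCatch(compute_features(f, ibi, cfg), error = function(e) NULL)
      if (is.null(row)) return(NULL)
      row$frame_start_s <- (f$start_sample - 1) / ibi$fs
      row
    })
    feats <- Filter(Negate(is.null), feats)
    if (!length(feats)) return(NULL)
    out <- do.call(rbind, feats)
    out$label <- blk$label
    out$subject_id <- rec$subject_id
    out$block_id <- rec$record_id
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(hrmad = numeric(0), rmssd = numeric(0),
                      iqrnn = numeric(0), mcvnn = numeric(0),
                      cvnn = numeric(0), cvsd = numeric(0), hti = numeric(0),
                      frame_start_s = numeric(0), label = character(0),
                      subject_id = character(0), block_id = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$block_id, out$frame_start_s), ]
  rownames(out) <- NULL
  out
}
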