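# Shared fixtures, all built in code.

# Noiseless waveform from an explicit RR sequence.
render_rr <- function(rr_ms, fs = 128, modality = "ECG", snr_db = Inf,
                      seed = 1) {
  spec <- synthetic_spec("NSR", duration_s = sum(rr_ms) / 1000, fs = fs,
                         modality = modality, noise_snr_db = snr_db,
                         seed = seed)
  render_waveform(rr_ms, spec, subject_id = "fixture")
}

# Constant-rate pulse train (the canonical clean fixture).
constant_train <- function(n_beats = 25, rr_ms = 800, fs = 128,
                           modality = "ECG", snr_db = Inf, seed = 1) {
  render_rr(rep(rr_ms, n_beats), fs, modality, snr_db, seed)
}

# Peak series straight from ground truth (bypasses detection).
truth_peaks <- function(rend, fs) {
  peak_series(rend$truth_peaks, fs,
              rend$recording$samples[rend$truth_peaks])
}

# Naive per-feature oracles: straightforward loops, independent of the
# package implementation.
naive_features <- function(nn, bin_ms = 1000 / 128) {
  n <- length(nn)
  sq <- 0
  for (i in 2:n) sq <- sq + (nn[i] - nn[i - 1])^2
  rmssd <- sqrt(sq / (n - 1))
  mu <- sum(nn) / n
  hrmad <- sum(abs(nn - mu)) / n
  counts <- table(floor(nn / bin_ms))
  list(
    hrmad = hrmad,
    rmssd = rmssd,
    iqrnn = unname(quantile(nn, 0.75, type = 7) - quantile(nn, 0.25, type = 7)),
    mcvnn = hrmad / median(nn),
    cvnn = sd(nn) / mu,
    cvsd = rmssd / mu,
    hti = n / max(counts)
  )
}

# Brute-force spike counter over successive interval differences.
naive_spike_count <- function(intervals_ms, threshold_ms) {
  cnt <- 0L
  for (i in 2:length(intervals_ms)) {
    if (abs(intervals_ms[i] - intervals_ms[i - 1]) > threshold_ms) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# Minimal frame/ibi pair from a bare interval sequence (unit tests of the
# frame statistics without a waveform).
ibi_from_intervals <- function(intervals_ms, fs = 250) {
  idx <- cumsum(c(1, round(intervals_ms * fs / 1000)))
  peaks <- peak_series(idx, fs, rep(1, length(idx)))
  build_ibi(peaks, max(idx) + 10L)
}

frame_over <- function(ibi) {
  structure(list(start_sample = 1L,
                 end_sample = ibi$record_len + 1L,
                 peak_indices = ibi$peak_indices),
            class = "reliable_frame")
}
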