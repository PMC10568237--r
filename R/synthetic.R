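#' Specification of a synthetic beat stream
#'
#' Describes one synthetic recording: rhythm class, duration, modality and
#' the beat-timing model parameters. Sinus rhythm is a mean interval plus
#' respiratory sinus-arrhythmia (RSA) modulation plus Gaussian jitter;
#' fibrillation is i.i.d. draws from a right-shifted Gamma — the simplest
#' model with the operative AFIB signature, large uncorrelated successive
#' interval differences. Isolated ectopy is emulated by a premature beat
#' with a compensatory pause.
#'
#' @param rhythm "NSR" or "AFIB".
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz for rendered waveforms.
#' @param modality "ECG" or "PPG".
#' @param mean_rr_ms mean beat interval, ms.
#' @param rr_jitter_ms NSR beat-to-beat Gaussian jitter SD, ms.
#' @param rr_sigma_ms AFIB interval SD, ms.
#' @param rsa_depth_ms amplitude of the RSA sinusoidal modulation, ms.
#' @param rsa_freq_hz RSA (breathing) frequency, Hz.
#' @param ectopic_rate_per_min expected isolated ectopic beats per minute.
#' @param noise_snr_db additive white-noise level as signal-to-noise ratio
#'   in dB measured in the 0.5-10 Hz cardiac band; `Inf` for noiseless.
#' @param seed mandatory integer seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(rhythm = c("NSR", "AFIB"), duration_s = 60,
                           fs = 128, modality = c("ECG", "PPG"),
                           mean_rr_ms = 800, rr_jitter_ms = 20,
                           rr_sigma_ms = 150, rsa_depth_ms = 25,
                           rsa_freq_hz = 0.25, ectopic_rate_per_min = 0,
                           noise_snr_db = Inf, seed) {
  rhythm <- match.arg(rhythm)
  modality <- match.arg(modality)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(duration_s > 0, fs > 0, mean_rr_ms >= 270, mean_rr_ms <= 1500,
            rr_jitter_ms >= 0, rr_sigma_ms > 0, rsa_depth_ms >= 0,
            rsa_freq_hz > 0, ectopic_rate_per_min >= 0)
  structure(
    list(rhythm = rhythm, duration_s = duration_s, fs = fs,
         modality = modality, mean_rr_ms = mean_rr_ms,
         rr_jitter_ms = rr_jitter_ms, rr_sigma_ms = rr_sigma_ms,
         rsa_depth_ms = rsa_depth_ms, rsa_freq_hz = rsa_freq_hz,
         ectopic_rate_per_min = ectopic_rate_per_min,
         noise_snr_db = noise_snr_db, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic RR sequence
#'
#' NSR: `rr_t = mean + rsa_depth * sin(2 pi rsa_freq t) + N(0, jitter^2)`
#' with `t` the cumulative beat time, truncated to physiological bounds.
#' AFIB: i.i.d. right-shifted Gamma with the requested mean and SD and no
#' serial correlation (shift `mean - 2 sd`, floored at 250 ms). Ectopic
#' beats replace `(rr_i, rr_{i+1})` by `(0.6 rr_i, 1.4 rr_{i+1})` — a
#' premature beat followed by a compensatory pause.
#'
#' @param spec a [synthetic_spec()].
#' @return numeric vector of intervals in ms covering `duration_s`.
#' @export
generate_rr <- function(spec) {
  with_local_seed(spec$seed, {
    total_ms <- spec$duration_s * 1000
    n_max <- ceiling(total_ms / 250) + 2L
    if (spec$rhythm == "NSR") {
      rr <- numeric(n_max)
      t_ms <- 0
      k <- 0L
      while (t_ms < total_ms && k < n_max) {
        k <- k + 1L
        v <- spec$mean_rr_ms +
          spec$rsa_depth_ms * sin(2 * pi * spec$rsa_freq_hz * t_ms / 1000) +
          rnorm(1, 0, spec$rr_jitter_ms)
        rr[k] <- min(1500, max(270, v))
        t_ms <- t_ms + rr[k]
      }
      rr <- rr[seq_len(k)]
    } else {
      shift <- max(250, spec$mean_rr_ms - 2 * spec$rr_sigma_ms)
      mu <- spec$mean_rr_ms - shift
      shape <- (mu / spec$rr_sigma_ms)^2
      scale <- spec$rr_sigma_ms^2 / mu
      rr <- numeric(0)
      while (sum(rr) < total_ms) {
        draw <- shift + rgamma(n_max, shape = shape, scale = scale)
        rr <- c(rr, pmin(1500, draw))
        if (length(rr) > 10 * n_max) break
      }
      rr <- rr[seq_len(which(cumsum(rr) >= total_ms)[1])]
    }
    if (spec$ectopic_rate_per_min > 0 && length(rr) > 2) {
      p <- spec$ectopic_rate_per_min / 60 * spec$mean_rr_ms / 1000
      hit <- which(rbinom(length(rr) - 1L, 1, min(1, p)) == 1)
      for (i in hit) {
        rr[i] <- 0.6 * rr[i]
        rr[i + 1L] <- 1.4 * rr[i + 1L]
      }
    }
    rr
  })
}

# Unit-peak pulse templates. ECG: narrow Gaussian R-spike (sigma ~12 ms).
# PPG: asymmetric gamma-shaped systolic pulse, shifted so its maximum sits
# at the nominal beat time (the "peak" ground truth).
pulse_template <- function(modality, fs) {
  if (modality == "ECG") {
    sigma <- 0.012
    tt <- seq(-4 * sigma, 4 * sigma, by = 1 / fs)
    list(shape = exp(-tt^2 / (2 * sigma^2)), center = which.min(abs(tt)))
  } else {
    shape_k <- 3
    rate <- 12
    tt <- seq(0, 0.7, by = 1 / fs)
    y <- (tt * rate)^(shape_k - 1) * exp(-tt * rate)
    y <- y / max(y)
    list(shape = y, center = which.max(y))
  }
}

#' Render a waveform from an RR sequence
#'
#' Places one pulse per beat (narrow Gaussian R-spike for ECG, asymmetric
#' gamma-shaped systolic pulse for PPG) on a zero baseline and adds white
#' noise scaled so the ratio of cardiac-band (0.5-10 Hz) signal power to
#' in-band noise power equals `noise_snr_db`. Ground-truth peak positions
#' are returned alongside the recording.
#'
#' @param rr RR intervals in ms.
#' @param spec a [synthetic_spec()] (fs, modality, noise level, seed).
#' @param subject_id,record_id identifiers for the resulting recording.
#' @return list with `recording`, `truth_peaks` (sample indices) and
#'   `rr_ms`.
#' @export
render_waveform <- function(rr, spec, subject_id = "synth",
                            record_id = "synth") {
  stopifnot(length(rr) >= 1)
  fs <- spec$fs
  beat_t <- 0.5 + cumsum(c(0, rr[-length(rr)])) / 1000
  n <- ceiling((0.5 + sum(rr) / 1000 + 0.5) * fs)
  x <- numeric(n)
  tpl <- pulse_template(spec$modality, fs)
  half_before <- tpl$center - 1L
  truth <- integer(length(beat_t))
  for (b in seq_along(beat_t)) {
    c_idx <- round(beat_t[b] * fs) + 1L
    truth[b] <- c_idx
    s <- c_idx - half_before
    e <- s + length(tpl$shape) - 1L
    lo <- max(1L, s)
    hi <- min(n, e)
    if (lo > hi) next
    x[lo:hi] <- x[lo:hi] + tpl$shape[(lo - s + 1L):(hi - s + 1L)]
  }
  if (is.finite(spec$noise_snr_db)) {
    ps <- welch_psd(x, fs)
    band <- ps$freq >= 0.5 & ps$freq <= 10
    df <- ps$freq[2] - ps$freq[1]
    p_band <- sum(ps$psd[band]) * df
    # white noise of variance s2 has one-sided PSD 2*s2/fs; in-band power
    # = s2 * 2 * 9.5 / fs
    s2 <- p_band / 10^(spec$noise_snr_db / 10) * fs / (2 * 9.5)
    x <- x + with_local_seed(spec$seed + 1L, rnorm(n, 0, sqrt(s2)))
  }
  rec <- recording(x, fs, spec$modality, subject_id, record_id)
  list(recording = rec, truth_peaks = truth, rr_ms = rr)
}

#' Generate a labelled synthetic cohort
#'
#' One single-rhythm block per subject, with per-subject beat-model
#' parameters drawn from physiologic ranges: NSR mean RR 700-1000 ms,
#' jitter 10-25 ms, RSA depth 10-30 ms at 0.18-0.3 Hz, up to 1 ectopic
#' beat/min; AFIB mean RR 600-900 ms, interval SD 120-180 ms. Waveforms
#' are rendered at 30 dB in-band SNR. Deterministic given the seed; each
#' subject draws from its own derived substream.
#'
#' @param n_subjects number of subjects (at least 2).
#' @param prevalence fraction of AFIB subjects in (0, 1); the AFIB count is
#'   `round(prevalence * n_subjects)`.
#' @param seed integer seed.
#' @param duration_s per-subject recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param modality "ECG" or "PPG".
#' @param noise_snr_db in-band SNR of the rendered waveforms, dB.
#' @return list with `blocks` (list of `rhythm_block`) and `truth`
#'   (data.frame subject_id, label, and the drawn parameters).
#' @export
make_cohort <- function(n_subjects, prevalence = 0.5, seed,
                        duration_s = 60, fs = 128, modality = "ECG",
                        noise_snr_db = 30) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  stopifnot(prevalence > 0, prevalence < 1)
  n_afib <- round(prevalence * n_subjects)
  labels <- with_local_seed(seed, {
    sample(c(rep("AFIB", n_afib), rep("NSR", n_subjects - n_afib)))
  })
  blocks <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    sub_seed <- derive_seed(seed, i)
    pars <- with_local_seed(sub_seed, {
      if (labels[i] == "NSR") {
        list(mean_rr_ms = runif(1, 700, 1000),
             rr_jitter_ms = runif(1, 10, 25),
             rsa_depth_ms = runif(1, 10, 30),
             rsa_freq_hz = runif(1, 0.18, 0.3),
             ectopic_rate_per_min = runif(1, 0, 1),
             rr_sigma_ms = 150)
      } else {
        list(mean_rr_ms = runif(1, 600, 900),
             rr_sigma_ms = runif(1, 120, 180),
             rr_jitter_ms = 20, rsa_depth_ms = 0, rsa_freq_hz = 0.25,
             ectopic_rate_per_min = 0)
      }
    })
    spec <- synthetic_spec(
      rhythm = labels[i], duration_s = duration_s, fs = fs,
      modality = modality, mean_rr_ms = pars$mean_rr_ms,
      rr_jitter_ms = pars$rr_jitter_ms, rr_sigma_ms = pars$rr_sigma_ms,
      rsa_depth_ms = pars$rsa_depth_ms, rsa_freq_hz = pars$rsa_freq_hz,
      ectopic_rate_per_min = pars$ectopic_rate_per_min,
      noise_snr_db = noise_snr_db, seed = derive_seed(sub_seed, 1)
    )
    rr <- generate_rr(spec)
    rend <- render_waveform(rr, spec, subject_id = sid, record_id = sid)
    blocks[[i]] <- structure(
      list(recording = rend$recording, label = labels[i],
           source_record = sid,
           source_interval = c(0L, length(rend$recording$samples))),
      class = "rhythm_block"
    )
    truth[[i]] <- data.frame(
      subject_id = sid, label = labels[i], mean_rr_ms = pars$mean_rr_ms,
      rr_jitter_ms = pars$rr_jitter_ms, rr_sigma_ms = pars$rr_sigma_ms,
      rsa_depth_ms = pars$rsa_depth_ms,
      ectopic_rate_per_min = pars$ectopic_rate_per_min,
      stringsAsFactors = FALSE
    )
  }
  list(blocks = blocks, truth = do.call(rbind, truth))
}
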