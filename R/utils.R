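# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All package randomness funnels through this.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed for hierarchical generation (cohort -> subject).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 9973 * as.numeric(index)) %% 2147483647)
}

# Bandlimited resampling in the frequency domain: truncate (or zero-pad) the
# spectrum to the target length. Exact for bandlimited periodic content;
# standard FFT-method resampler.
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  m <- min(n, n_out)
  k <- floor(m / 2)
  Y[seq_len(k + 1)] <- X[seq_len(k + 1)]
  if (k >= 1) Y[(n_out - k + 1):n_out] <- X[(n - k + 1):n]
  # split the shared Nyquist bin when the smaller length is even
  if (m %% 2 == 0) {
    if (n_out < n) {
      Y[k + 1] <- X[k + 1] + X[n - k + 1]
    } else {
      Y[k + 1] <- X[k + 1] / 2
      Y[n_out - k + 1] <- X[k + 1] / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

# Welch PSD: mean of Hann-windowed modified periodograms, 50% overlap.
# Returns one-sided density over freq in Hz. Segment length in samples.
welch_psd <- function(x, fs, nseg = NULL) {
  n <- length(x)
  if (is.null(nseg)) nseg <- min(n, max(256L, 2L^floor(log2(n / 4))))
  nseg <- min(nseg, n)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  norm <- sum(w^2) * fs
  nfreq <- floor(nseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / norm
    acc <- acc + P[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # double interior bins for one-sided density
  interior <- 2:(nfreq - if (nseg %% 2 == 0) 1L else 0L)
  psd[interior] <- 2 * psd[interior]
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = psd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
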