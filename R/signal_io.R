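#' Construct a waveform recording
#'
#' The basic container passed through the whole pipeline: a uniformly
#' sampled single-channel waveform with its sampling rate, modality and
#' identifiers. `subject_id` is required because train/test splitting is
#' done by subject, never by row.
#'
#' @param samples numeric vector of amplitudes (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param modality "ECG" or "PPG".
#' @param subject_id,record_id opaque identifier strings.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, fs, modality = c("ECG", "PPG"),
                      subject_id = "anon", record_id = "rec") {
  modality <- match.arg(modality)
  samples <- as.numeric(samples)
  if (!length(samples)) stop("no samples", call. = FALSE)
  if (anyNA(samples)) stop("samples contain NA", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  if (!nzchar(subject_id)) stop("subject_id must be non-empty", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, modality = modality,
         subject_id = as.character(subject_id),
         record_id = as.character(record_id)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s> %s, %d samples @ %g Hz (%.1f s), subject %s\n",
              x$record_id, x$modality, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$subject_id))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @return duration in seconds.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$fs

#' Read a waveform record from disk
#'
#' Accepts a WFDB header (`.hea`, with its format-16 `.dat` signal file
#' beside it; first channel used) or a CSV file of either two columns
#' (time in seconds, amplitude) or one column (amplitude, requiring
#' `fs_override`). A header row is detected and skipped. For two-column
#' CSV the sampling rate is inferred as `1 / median(diff(time))`.
#'
#' @param path file path (`.hea` or CSV/TSV text).
#' @param modality "ECG" or "PPG".
#' @param fs_override sampling rate in Hz, mandatory for single-column CSV,
#'   otherwise overrides the inferred/header rate.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return a [recording()].
#' @export
read_record <- function(path, modality = c("ECG", "PPG"), fs_override = NULL,
                        subject_id = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stem <- tools::file_path_sans_ext(basename(path))
  subject_id <- subject_id %||% stem
  if (grepl("\\.hea$", path, ignore.case = TRUE)) {
    rec <- read_wfdb(path)
    fs <- fs_override %||% rec$fs
    return(recording(rec$samples, fs, modality, subject_id, stem))
  }
  df <- tryCatch(
    read.csv(path, header = FALSE, stringsAsFactors = FALSE,
             blank.lines.skip = TRUE),
    error = function(e) stop("no samples in ", path, call. = FALSE))
  if (!nrow(df)) stop("no samples in ", path, call. = FALSE)
  # drop a non-numeric header row if present
  first_num <- suppressWarnings(as.numeric(unlist(df[1, ])))
  if (anyNA(first_num)) df <- df[-1, , drop = FALSE]
  if (!nrow(df)) stop("no samples in ", path, call. = FALSE)
  num <- vapply(df, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df))
  if (ncol(num) >= 2) {
    tt <- num[, 1]; amp <- num[, 2]
    dt <- median(diff(tt))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer fs from time column",
                                        call. = FALSE)
    fs <- fs_override %||% (1 / dt)
  } else {
    if (is.null(fs_override)) {
      stop("single-column CSV requires fs_override", call. = FALSE)
    }
    amp <- num[, 1]; fs <- fs_override
  }
  recording(amp, fs, modality, subject_id, stem)
}

# Minimal WFDB reader: text header + format-16 (16-bit little-endian,
# interleaved) signal file. Amplitudes are returned in raw ADC units,
# first channel only.
read_wfdb <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("unparseable WFDB header", call. = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 3) stop("unparseable WFDB header", call. = FALSE)
  nsig <- as.integer(hdr[2])
  fs <- as.numeric(hdr[3])
  nsamp <- if (length(hdr) >= 4) as.integer(hdr[4]) else NA_integer_
  if (is.na(nsig) || is.na(fs) || nsig < 1 || fs <= 0) {
    stop("unparseable WFDB header", call. = FALSE)
  }
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  dat_file <- sig[1]
  fmt <- sub("x.*$", "", sig[2])
  if (fmt != "16") stop("unsupported WFDB signal format: ", sig[2],
                        call. = FALSE)
  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path,
                                   call. = FALSE)
  n_int <- file.size(dat_path) / 2
  raw <- readBin(dat_path, "integer", n = n_int, size = 2,
                 endian = "little", signed = TRUE)
  x <- raw[seq(1, length(raw), by = nsig)]
  if (!is.na(nsamp) && nsamp > 0) x <- x[seq_len(min(nsamp, length(x)))]
  if (!length(x)) stop("no samples", call. = FALSE)
  list(samples = as.numeric(x), fs = fs)
}

#' Rhythm annotation intervals
#'
#' Labelled rhythm intervals over a recording, as half-open 0-based sample
#' ranges `[start, end)`. Can be read from a CSV with columns
#' `start,end,label` via [read_annotation()].
#'
#' @param start,end integer sample indices, half-open `[start, end)`.
#' @param label character labels among "NSR", "AFIB", "OTHER".
#' @return a `data.frame` of class `rhythm_annotation`, sorted by start.
#' @export
rhythm_annotation <- function(start, end, label) {
  stopifnot(length(start) == length(end), length(end) == length(label))
  label <- as.character(label)
  bad <- setdiff(unique(label), c("NSR", "AFIB", "OTHER"))
  if (length(bad)) stop("unknown rhythm labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = label, stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
    stop("annotation intervals overlap", call. = FALSE)
  }
  class(df) <- c("rhythm_annotation", "data.frame")
  df
}

#' Read rhythm annotations from CSV
#' @param path CSV with columns start, end, label (half-open sample ranges).
#' @return a [rhythm_annotation()].
#' @export
read_annotation <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  rhythm_annotation(df$start, df$end, df$label)
}

#' Cut a recording into single-rhythm blocks
#'
#' Slices a long recording at its annotation boundaries so that each
#' contiguous single-rhythm interval becomes an independent sample, the way
#' long ambulatory records are split into NSR and AFIB events for
#' evaluation. Intervals with labels outside `keep` are dropped.
#'
#' @param rec a [recording()].
#' @param ann a [rhythm_annotation()].
#' @param keep labels to retain (default NSR and AFIB).
#' @return list of `rhythm_block` objects, each holding the sliced
#'   `recording`, its `label`, and the source record/interval.
#' @export
split_by_rhythm <- function(rec, ann, keep = c("NSR", "AFIB")) {
  n <- length(rec$samples)
  if (nrow(ann) && any(ann$end > n)) {
    stop("annotation interval exceeds record length", call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(ann))) {
    lab <- ann$label[i]
    if (!(lab %in% keep) || lab == "OTHER") next
    # half-open [start, end) in 0-based samples -> 1-based R slice
    slice <- rec$samples[(ann$start[i] + 1L):ann$end[i]]
    sub <- recording(slice, rec$fs, rec$modality, rec$subject_id,
                     sprintf("%s_blk%d", rec$record_id, i))
    out[[length(out) + 1L]] <- structure(
      list(recording = sub, label = lab, source_record = rec$record_id,
           source_interval = c(ann$start[i], ann$end[i])),
      class = "rhythm_block"
    )
  }
  out
}

#' @export
print.rhythm_block <- function(x, ...) {
  cat(sprintf("<rhythm_block %s> label %s, samples [%d, %d) of %s\n",
              x$recording$record_id, x$label, x$source_interval[1],
              x$source_interval[2], x$source_record))
  invisible(x)
}

#' Segment a recording into fixed windows
#'
#' Contiguous (optionally overlapping) fixed-length windows; a final
#' partial window is dropped. Returns an empty list when the record is
#' shorter than one window.
#'
#' @param rec a [recording()].
#' @param window_s window length in seconds.
#' @param overlap_s overlap between consecutive windows in seconds.
#' @return list of `recording` windows.
#' @export
segment_fixed <- function(rec, window_s, overlap_s = 0) {
  stopifnot(window_s > 0, overlap_s >= 0, overlap_s < window_s)
  wn <- round(window_s * rec$fs)
  step <- round((window_s - overlap_s) * rec$fs)
  n <- length(rec$samples)
  if (n < wn) return(list())
  starts <- seq(1L, n - wn + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    recording(rec$samples[s:(s + wn - 1L)], rec$fs, rec$modality,
              rec$subject_id, sprintf("%s_w%d", rec$record_id, i))
  })
}

#' Anti-aliased downsampling
#'
#' Resamples in the frequency domain (spectrum truncation), which both
#' band-limits and resamples in one exact step; used e.g. to bring PPG
#' waveforms to 50 Hz. Output length is `round(n * target_fs / fs)`.
#'
#' @param rec a [recording()].
#' @param target_fs target sampling rate in Hz, at most `rec$fs`.
#' @return a [recording()] at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  if (!is.numeric(target_fs) || target_fs <= 0) {
    stop("target_fs must be positive", call. = FALSE)
  }
  if (target_fs > rec$fs) stop("target_fs exceeds current fs", call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  n_out <- round(length(rec$samples) * target_fs / rec$fs)
  y <- resample_fft(rec$samples, n_out)
  recording(y, target_fs, rec$modality, rec$subject_id, rec$record_id)
}
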