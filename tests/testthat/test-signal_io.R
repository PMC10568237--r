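test_that("CSV records read back with explicit or inferred sampling rate", {
  amp <- sin(seq(0, 10, length.out = 500))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(amplitude = amp), f1, row.names = FALSE)
  rec <- read_record(f1, "ECG", fs_override = 250)
  expect_s3_class(rec, "recording")
  expect_length(rec$samples, 500)
  expect_equal(rec$fs, 250)
  expect_equal(rec$samples, amp)

  # two-column: 4 ms spacing -> 250 Hz inferred
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time = (0:499) * 0.004, amplitude = amp), f2,
            row.names = FALSE)
  rec2 <- read_record(f2, "PPG")
  expect_equal(rec2$fs, 250)
  expect_equal(rec2$modality, "PPG")

  # single column without fs is an error; empty file is an error
  expect_error(read_record(f1, "ECG"), "fs_override")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f3)
  expect_error(read_record(f3, "ECG", fs_override = 100), "no samples")
  expect_error(read_record(file.path(tempdir(), "nope.csv"), "ECG"),
               "not found")
})

test_that("WFDB format-16 header/signal pairs round-trip", {
  dir <- withr::local_tempdir()
  x <- as.integer(round(2000 * sin(2 * pi * (0:999) / 100)))
  writeBin(x, file.path(dir, "rec01.dat"), size = 2, endian = "little")
  writeLines(c("rec01 1 250 1000", "rec01.dat 16 200 12 0 0 0 0 ECG"),
             file.path(dir, "rec01.hea"))
  rec <- read_record(file.path(dir, "rec01.hea"), "ECG")
  expect_equal(rec$fs, 250)
  expect_equal(rec$samples, as.numeric(x))

  # two interleaved channels: first one is used
  y <- as.vector(rbind(x, rep(7L, 1000)))
  writeBin(y, file.path(dir, "rec02.dat"), size = 2, endian = "little")
  writeLines(c("rec02 2 128 1000",
               "rec02.dat 16 200 12 0 0 0 0 ECG",
               "rec02.dat 16 200 12 0 0 0 0 other"),
             file.path(dir, "rec02.hea"))
  rec2 <- read_record(file.path(dir, "rec02.hea"), "ECG")
  expect_equal(rec2$samples, as.numeric(x))
  expect_equal(rec2$fs, 128)

  writeLines("garbage", file.path(dir, "bad.hea"))
  expect_error(read_record(file.path(dir, "bad.hea"), "ECG"), "header")
})

test_that("rhythm splitting honours half-open intervals and label filters", {
  rec <- recording(seq_len(20000), 250, "ECG", subject_id = "s1",
                   record_id = "r1")
  ann <- rhythm_annotation(c(0, 10000), c(10000, 20000), c("NSR", "AFIB"))
  blocks <- split_by_rhythm(rec, ann)
  expect_length(blocks, 2)
  expect_equal(vapply(blocks, `[[`, character(1), "label"),
               c("NSR", "AFIB"))
  # half-open: no gap, no overlap, reconstruction covers the index space
  expect_equal(blocks[[1]]$recording$samples, 1:10000)
  expect_equal(blocks[[2]]$recording$samples, 10001:20000)
  expect_equal(length(blocks[[1]]$recording$samples) +
                 length(blocks[[2]]$recording$samples), 20000)

  expect_length(split_by_rhythm(rec, ann, keep = "AFIB"), 1)
  empty <- rhythm_annotation(integer(0), integer(0), character(0))
  expect_length(split_by_rhythm(rec, empty), 0)
  # OTHER dropped even when kept explicitly
  ann2 <- rhythm_annotation(0, 5000, "OTHER")
  expect_length(split_by_rhythm(rec, ann2, keep = c("NSR", "AFIB", "OTHER")),
                0)
  bad <- rhythm_annotation(0, 30000, "NSR")
  expect_error(split_by_rhythm(rec, bad), "exceeds")
})

test_that("annotation validation rejects overlap and bad labels", {
  expect_error(rhythm_annotation(c(0, 500), c(1000, 1500), c("NSR", "AFIB")),
               "overlap")
  expect_error(rhythm_annotation(0, 100, "WEIRD"), "unknown")
  expect_error(rhythm_annotation(10, 10, "NSR"), "start < end")
})

test_that("fixed segmentation drops the partial tail and tiles exactly", {
  rec <- recording(rnorm(95 * 100), 100, "ECG")
  segs <- segment_fixed(rec, 30)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) length(s$samples), numeric(1)) ==
                    3000))
  expect_length(segment_fixed(recording(rnorm(3000), 100, "ECG"), 30), 1)
  expect_length(segment_fixed(recording(rnorm(2900), 100, "ECG"), 30), 0)
  # non-overlapping starts differ by exactly window * fs samples
  rec2 <- recording(rnorm(1000), 10, "ECG")
  segs2 <- segment_fixed(rec2, 20)
  total <- sum(vapply(segs2, function(s) length(s$samples), numeric(1)))
  expect_lte(total, length(rec2$samples))
  # with overlap, step shrinks
  segs3 <- segment_fixed(rec2, 20, overlap_s = 10)
  expect_length(segs3, 9)
})

test_that("downsampling is anti-aliased and exact on bandlimited input", {
  # 1 Hz sine, whole number of periods: spectrum truncation is exact
  t <- (0:1249) / 125
  rec <- recording(sin(2 * pi * t), 125, "PPG")
  ds <- downsample(rec, 50)
  expect_equal(ds$fs, 50)
  expect_length(ds$samples, 500)
  truth <- sin(2 * pi * (0:499) / 50)
  trim <- 26:475
  expect_lt(max(abs(ds$samples[trim] - truth[trim])), 1e-6)

  expect_identical(downsample(rec, 125)$samples, rec$samples)
  expect_error(downsample(rec, 200), "exceeds")
  expect_error(downsample(rec, -5), "positive")

  # high-frequency content is removed, not folded: 30 Hz tone at 125 Hz
  # must not appear in the 50 Hz output (Nyquist 25 Hz)
  rec2 <- recording(sin(2 * pi * 30 * t) + sin(2 * pi * 2 * t), 125, "PPG")
  ds2 <- downsample(rec2, 50)
  resid <- ds2$samples - sin(2 * pi * 2 * (0:499) / 50)
  expect_lt(max(abs(resid[trim])), 1e-6)
})
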