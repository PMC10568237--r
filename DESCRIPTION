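Package: afibkit
Title: Atrial Fibrillation Screening from Short ECG and PPG Beat Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two complementary short-window atrial-fibrillation detectors
    operating on inter-beat-interval (IBI) series extracted from single-channel
    ECG or photoplethysmography (PPG) recordings: a training-free
    signal-processing detector that thresholds first-derivative spikes of the
    IBI signal, and a machine-learning detector built on seven heart-rate
    variability features with subject-wise splits and per-sample frame voting.
    Includes waveform preprocessing (Savitzky-Golay smoothing, zero-phase
    Butterworth band-pass, scaled min-max normalization), adaptive beat
    detection with double-peak correction, physiological-bounds interval
    validation, a two-step signal-quality gate (valid-peak fraction and
    spectral SNR), confusion-matrix metrics, and a seeded synthetic generator
    of sinus-rhythm and fibrillation beat sequences and waveforms so the whole
    pipeline is testable without physiological databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    e1071,
    class,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
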