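---
title: "Detecting atrial fibrillation from short beat streams: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation from short beat streams: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afibkit)
```

## The problem

Atrial fibrillation (AFIB) is the most common sustained arrhythmia. Its
electrophysiological hallmark — the absent P wave — requires a clean ECG,
but its *mechanical* signature, an irregularly irregular ventricular
response, is visible in nothing more than the sequence of inter-beat
intervals (IBI). That makes screening possible from any sensor that can
time heartbeats, including wrist-worn photoplethysmography (PPG). Because
paroxysmal AFIB comes and goes, a detector must work on short windows
(seconds, not hours) and tolerate the artifact burden of ambulatory
signals.

`afibkit` implements two complementary short-window detectors on a shared
beat-extraction front end:

* a **training-free signal-processing (DSP) detector** that thresholds
  spikes in the first derivative of the IBI sequence, and
* a **machine-learning detector** on seven per-window heart-rate
  variability (HRV) features, aggregated to one label per recording by
  majority vote.

## Shared front end

1. **Smoothing** — Savitzky–Golay, order 4, 19-sample window. A local
   polynomial fit suppresses wideband noise while leaving the sharp QRS
   complex (locally well approximated by a low-order polynomial)
   untouched. The 19-sample window is kept fixed across sampling rates by
   default; a per-rate override exists in `afib_config()` because the
   effective time width of a fixed sample count shrinks as `fs` grows.
2. **Band-pass** — 2nd-order Butterworth, 0.5–20 Hz, applied
   forward–backward (`filtfilt`). Zero-phase application matters more
   here than a textbook magnitude response: every downstream quantity is
   a *peak time*, and a causal IIR filter would shift peaks by a
   frequency-dependent group delay. The forward–backward pass doubles the
   effective order; we accept that, since the passband is generous. At
   low sampling rates (50 Hz PPG) the upper cutoff is clamped to
   `0.4 * fs` to stay below Nyquist.
3. **Normalization** — affine min–max onto `[0, 10]`. A constant segment
   has no dynamic range and is rejected outright; the quality gate exists
   to stop such segments earlier.
4. **Beat detection** — local maxima above an adaptive threshold of half
   the rolling 2-s block maximum, thinned with a 0.27 s refractory
   distance (larger peak wins). The block maximum, not a mid-range
   quantile, is the right local reference: an R spike occupies only a few
   percent of samples, so amplitude quantiles sit near the baseline and
   would let noise bumps through, whereas every 2-s block contains at
   least one true beat at physiological rates. The threshold is floored
   at a quarter of the global maximum so that beat-free edges of a
   recording cannot threshold on noise. A **double-peak correction** pass
   removes the smaller of any two detections closer than 250 ms,
   iterating to a fixed point.
5. **IBI validation** — each interval is kept only if it lies within
   physiological bounds, by default 270–1500 ms (about 40–220 bpm: the
   270 ms floor matches the ventricular refractory period, the 1500 ms
   ceiling flags dropped beats). The bounds are configurable because they
   are conventional artifact limits, not constants of nature. Invalid
   intervals are zeroed in the sample-expanded masked view and excluded
   from analysis frames. The sample-aligned expansion is step-wise
   (sample-and-hold, each waveform sample carries the interval of the gap
   containing it) rather than interpolated, so interval values survive
   exactly into any sample-aligned representation.
6. **Reliable frames** — a sliding window is kept only when *no* interval
   it touches is invalid and at least two beats fall inside. All
   classification happens on reliable frames only.

## The DSP detector

Within each reliable 8-s frame (2-s stride) the detector takes successive
differences of the per-gap interval sequence in ms. A difference larger
than 50 ms in magnitude is an *abnormal spike*; the frame statistic is
`spikes / peaks-in-frame`, and a recording is called AFIB when the mean
ratio over frames exceeds a decision threshold.

Two numerical choices deserve comment:

* The derivative runs on the **per-gap sequence**, not the
  sample-expanded signal. On the expanded signal every rhythm change
  appears once per *sample* of the following gap, which would multiply
  spike counts by the sampling rate and rob the 50 ms threshold of its
  meaning.
* Frames with fewer than 3 peaks are skipped, not counted as zero-ratio:
  a frame that cannot produce a difference carries no evidence and should
  not dilute the mean.

The 50 ms spike threshold is a published operating constant. The decision
threshold on the mean ratio is not; the package ships a default of 0.15
together with `calibrate_dsp_threshold()`, which sweeps all candidate
cutoffs on labelled data and returns the Youden-optimal point
(max sensitivity + specificity − 1). The end-to-end evaluation
(`evaluate_synthetic()`, `scripts/acceptance.R`) calibrates on an
independent cohort before measuring, which mirrors how such an operating
point is set in practice: on the default synthetic populations the two
class distributions of mean ratios are widely separated (sinus rhythm
concentrates near 0–0.25, fibrillation near 0.5–0.75), so the calibrated
cutoff lands in the empty region between them, whereas a fixed 0.15
clips the upper tail of high-variability sinus subjects.

Whether the mean should run over all reliable frames or only frames with
at least one abnormal spike is ambiguous on its face; we average over
*all* reliable frames, since conditioning on having a spike would make
the statistic insensitive to how rare spikes are — precisely the quantity
that separates the rhythms.

## The HRV/ML detector

Per reliable 15-s frame (2-s stride), seven features of the NN intervals
(valid intervals, ms):

| feature | definition | unit |
|---|---|---|
| `hrmad` | mean absolute deviation of NN (default) or of 60000/NN | ms (or bpm) |
| `rmssd` | root mean square of successive NN differences | ms |
| `iqrnn` | inter-quartile range of NN (linear-interpolation quartiles, R type 7) | ms |
| `mcvnn` | `hrmad / median(NN)` | — |
| `cvnn`  | `sd(NN) / mean(NN)` (sample SD) | — |
| `cvsd`  | `rmssd / mean(NN)` | — |
| `hti`   | NN count / modal histogram bin count, bin width 1000/128 ms | — |

`hrmad` is described in the HRV literature both as a deviation of the
heart *rate* (bpm) and of the *intervals* (ms). We default to the ms
variant so that `mcvnn = hrmad / median(NN)` is dimensionless, which is
how coefficient-of-variation-style indices are meant to behave; the bpm
variant is one config switch away (`hrmad_on = "bpm"`) for anyone who
needs the other reading. The triangular-index bin width of 1/128 s is the
conventional HRV-standard histogram resolution. Quartile convention
matters for `iqrnn` (implementations differ by several ms on small
frames); we use linear interpolation and say so.

Frames need at least 5 valid intervals; sparser frames are dropped.

Three learners are wired in: random forest (300 trees — the package's
reference model), RBF-kernel SVM (C = 1) and KNN (k = 15), the latter two
on features standardized with training-set statistics only. The split is
**by subject, never by row**: sliding windows make neighbouring rows of
one person nearly identical, so a row-wise split would leak and inflate
every metric. `check_split_leakage()` asserts the invariant. Because
subjects carry different numbers of frames, a 60/40 subject split is
generally not a 60/40 row split — that asymmetry is intentional and
preserved.

Frame predictions are aggregated per recording by majority vote. An
exact tie goes to AFIB: in a screening context a false alarm costs a
confirmatory ECG, a miss costs a stroke risk. The tie rule is
configurable (`vote_tie`).

## The quality gate

PPG segments are screened before prediction by two layers:

1. **valid-peak fraction** — at least 75% of the segment's intervals must
   pass the physiological-bounds mask;
2. **SNR** — the mean signal-to-noise ratio must exceed 5 dB.

The SNR definition had to be pinned down for the 5 dB threshold to be
reproducible. We use a *beat-template* estimator: band-pass the waveform
to the cardiac band (0.5–10 Hz), cut a window of half the median interval
on each side of every detected beat (the windows tile the full cycle),
average them into an ensemble template, and report the mean over beats of
`10 log10(template power / residual power)`, clipped to ±60 dB. Two
properties drove this choice over a spectral (harmonic-comb) estimator:

* it is **rhythm-agnostic** — a clean fibrillating recording has a stable
  pulse *shape* even though its spectrum is smeared by rate variability,
  so it scores as clean, which the gate requires (rejecting clean AFIB
  segments would remove exactly the cases the pipeline exists to find);
* it is approximately **unbiased at the crossover** — white noise with
  in-band power equal to the in-band signal power reads ≈ 0 dB, so the
  5 dB threshold has a physical interpretation.

The test suite pins all of this down: clean constant-rate trains score
far above 20 dB, a rendered 30 dB recording is estimated within ±3 dB,
and adding noise can only lower the estimate.

## The synthetic generator

The generator stands in for annotated physiological databases in every
test. It emulates:

* **NSR**: `rr_t = mean + rsa_depth * sin(2 pi rsa_freq t) + N(0,
  jitter^2)`, truncated to the physiological bounds — mean interval plus
  respiratory sinus arrhythmia plus beat-to-beat jitter;
* **AFIB**: i.i.d. right-shifted Gamma intervals matched to a requested
  mean and SD (shift `mean − 2 SD`, floored at 250 ms). This is the
  simplest model with the operative signature — large, serially
  uncorrelated successive differences — and deliberately *not* a
  physiological atrioventricular-node model;
* **ectopy**: isolated premature beats with compensatory pauses,
  `(rr_i, rr_{i+1}) -> (0.6 rr_i, 1.4 rr_{i+1})` at a configurable rate;
* **waveforms**: one unit pulse per beat (narrow Gaussian R spike,
  sigma ≈ 12 ms, for ECG; an asymmetric gamma-shaped systolic pulse for
  PPG) plus white noise scaled to a requested in-band (0.5–10 Hz) SNR.

Cohorts draw per-subject parameters from physiologic ranges chosen once:
sinus subjects with mean RR 700–1000 ms, jitter 10–25 ms, RSA depth
10–30 ms at 0.18–0.3 Hz and up to one ectopic beat per minute;
fibrillating subjects with mean RR 600–900 ms and interval SD 120–180 ms;
waveforms at 30 dB. All randomness flows through one seed with derived
per-subject substreams, so cohorts are bit-reproducible.

What the generator does *not* emulate — and therefore what green tests do
**not** establish about real data: P-wave morphology and its absence,
atrial flutter and junctional rhythms, motion artifact with its
non-white, beat-correlated structure, baseline wander, sensor saturation,
and the long-tailed artifact burden of true ambulatory recordings. The
synthetic populations are also better separated than hospital datasets
(their published frame accuracies sit in the low-to-mid 90s, ours on
synthetic cohorts near 99): passing here validates the *mechanics* of the
pipeline — timing recovery, masking, feature arithmetic, split hygiene,
vote logic — not clinical performance.

## Degenerate inputs and tie-breaks

* Constant (zero-dynamic-range) segments error in normalization and are
  reported as `UNCLASSIFIABLE` by `classify_dsp()`, never as a rhythm.
* Recordings shorter than one analysis window yield no frames and are
  likewise `UNCLASSIFIABLE`.
* An all-negative evaluation (no AFIB cases) leaves precision/recall as
  flagged `NA` with a warning, never a silent 0.
* Equal-amplitude double peaks keep the earlier peak; `prob = 0.5` KNN
  ties and 50/50 votes fall to the AFIB side.
* Broadband noise without the quality gate can fool the DSP detector into
  an AFIB call — its intervals are random but can sit inside the
  physiological bounds. This is a known limitation of pure
  interval-irregularity detectors; the gate is the intended mitigation
  and is part of the PPG path.

## Problem sizes

The test suite and acceptance script size their simulations to desk
scale: cohorts of 40 subjects at 60 s each (about 75 beats per subject),
five evaluation seeds plus one calibration cohort, oracle sweeps of 1000
random interval vectors, and 128 Hz ECG / 50 Hz PPG sampling. These sizes
were chosen as the smallest at which the cohort-level statistics are
stable across seeds.
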