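---
title: "Contactless heart-rate tracking by video magnification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless heart-rate tracking by video magnification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

## The problem

Cardiac activity modulates the blood volume of facial skin, and with it the
light the skin reflects. The modulation is tiny — a fraction of a percent of
the pixel intensity range — but it is periodic at the heart rate, so it can
be pulled out of ordinary video of a face (RGB or single-channel infrared)
without any contact sensor. `pulsemag` implements a two-pass pipeline for
doing this, aimed at physiological monitoring of primates (and people)
sitting in front of a camera: magnify the in-band temporal variation,
read the heart rate off a wavelet ridge, narrow the band around that first
estimate, and repeat. The package also contains everything needed to
validate such an estimate against a simultaneously recorded ECG and to
quantify stimulus-evoked heart-rate changes.

## The processing model

### Eulerian video magnification

Writing the intensity at pixel `x` and time `t` as `I(x, t) = f(x + δ(t))`,
a small temporal displacement `δ(t)` of the underlying signal can be
amplified by synthesizing `Î(x, t) = f(x + (1 + α)δ(t))`. To first order,
that is achieved by adding `α` times the band-passed component of each
pixel's time series back to the video. `magnify()` implements the
Gaussian-pyramid variant:

1. spatial low-pass: `levels` rounds of separable binomial blur
   (`[1,4,6,4,1]/16`) and factor-2 decimation;
2. temporal filter: an ideal (brick-wall DFT) band-pass over the
   heart-rate band, zero-phase, unit gain in band and zero outside;
3. the filtered coarse-level signal is upsampled back by repeated
   factor-2 bilinear interpolation and added, scaled by `α`.

For a spatially uniform in-band luminance modulation of amplitude `A` the
output modulation is exactly `(1 + α)A`; out-of-band content is untouched
(`Î = I`), the temporal mean of every pixel is preserved (the band excludes
DC), and `α = 0` is the identity. These invariants are what the test suite
pins down, because every downstream stage depends on them.

The ideal filter is deliberately a hard DFT mask rather than an IIR design:
it has unit gain and zero phase by construction, at the cost of spectral
leakage at the sequence edges. Downstream estimates within a guard interval
of the clip ends (2 s, or one wavelet e-folding time if larger) are flagged
as edge-affected and excluded from summary statistics.

### Two-pass heart-rate extraction

`estimate_hr()` is the central fitting function and returns a classed
object with `print`/`summary`/`plot` methods:

1. crop to the region of interest (hairless facial skin works best; the
   package takes the rectangle as given and does not detect faces);
2. magnify over a broad physiological band, 90–200 BPM by default;
3. rank pixels by in-band temporal power (or mean luminosity) and keep the
   top fraction (default 10%); average those pixels per channel, then
   average the channels into one trace;
4. complex Morlet wavelet transform (center frequency 6) on a 0.5 BPM
   grid; the instantaneous rate is the peak-power frequency at each time
   step, ties resolving to the lower frequency;
5. the pass-1 approximation is the median of the interior instantaneous
   estimates — robust to transient mis-locks;
6. the band is narrowed to `approximation ± margin` and steps 2–4 are
   repeated, followed by a 20 s running average.

**Pass-2 margin.** The minimal half-width is 10 BPM. A fixed ±10 band is
correct for a steady rate but fails for a drifting one: a rate sweeping
100–140 BPM leaves a ±10 band around the median and the ridge gets clamped.
The estimator therefore widens the margin adaptively to
`max(10, 1.3 × max |pass-1 ridge − median| + 2 grid steps)`. The 30%
headroom is not cosmetic: a drifting rate is a frequency-modulated signal
whose spectrum extends beyond the swept range (Carson's rule), so a band
cut exactly at the observed excursion still truncates modulation energy
and biases the pass-2 ridge. With the headroom, the pass-2 ridge is at
least as accurate as pass 1 in every synthetic condition we test.
`adaptive_margin = FALSE` restores the fixed behaviour.

**Pixel selection.** Band-power ranking is the default because selecting
pixels by pulsatile content is what makes the averaged trace informative;
luminosity ranking is retained as an option since bright, well-lit skin is
a reasonable proxy when the band-power map is too noisy to rank.

### ECG ground truth

`detect_r_peaks()` is a Pan–Tompkins-style detector (5–30 Hz band-pass,
squared derivative, 120 ms integration window, adaptive threshold at 40%
of the running 95th-percentile amplitude, 0.25 s refractory — supporting
rates to 240 BPM). Instantaneous rate is `60/RR` placed at interval
midpoints, smoothed by the same 20 s running average as the video
estimate so the two series are comparable.

### Wavelet coherence validation

`wavelet_coherence()` computes squared coherence
`|S(W_x W_y^*/s)|² / (S(|W_x|²/s) · S(|W_y|²/s))` between the two rate
series, resampled to a common 1 Hz grid (heart rate varies slowly; its
fluctuations live below 0.5 Hz). The smoothing operator `S` is a boxcar of
one wavelet period per scale in time and 0.6 octaves in scale — without
smoothing, pointwise coherence is identically 1 and the statistic is
meaningless, which the test suite asserts explicitly by requiring the
estimator to separate a shared-sinusoid pair from an independent-noise
pair.

The scalar summary takes, at each interior time point (outside each
scale's cone of influence), the maximum coherence across frequencies, and
averages those maxima over time. The opposite order — per-frequency maxima
averaged across frequencies — is a documented config switch
(`order = "mean_of_freq_maxima"`), since either reading is defensible;
max-then-mean is the default because it asks "was there, at every moment,
*some* frequency at which the two rates co-varied?", which is the question
a validation against ECG poses. Note the null distribution of this
statistic is high (≈0.9 for independent smoothed rate series): a
max-over-frequency of a smoothed bounded quantity concentrates near its
ceiling, so paired recordings must be compared against a surrogate null,
not against 0.5.

`roi_coherence_map()` tiles the frame into a grid (default 10×10,
remainder pixels to the last row/column), reruns the full estimator per
cell and stores each cell's coherence against ECG — a spatial map of where
on the face the pulse is readable. Cells too small for the pyramid are
flagged invalid rather than fatal; the per-cell pyramid depth is capped by
the cell geometry.

### Stimulus-evoked heart-rate changes

`align_to_events()` interpolates the rate series onto a common
peristimulus grid (default [−16, +16] s around onset; events whose window
leaves the recording are dropped with a warning). `baseline_correct()`
subtracts each trial's [−13, −3] s mean. `pre_post_test()` compares
per-trial pre ([−13, −3] s) and post ([3, 13] s) window means with a
Wilcoxon rank-sum test (a paired signed-rank variant is available, since
trials are naturally paired). The test always uses uncorrected window
means: the baseline window coincides with the pre window, so testing
baseline-corrected means would compare exact zeros against noise — a
degenerate rank statistic whose false-positive rate is inflated (we
measured ≈10% at a nominal 5%). On uncorrected means the measured type-I
error is within the binomial band of 5%. The paired variant is invariant
to the choice, as per-trial constants cancel in post − pre.

Cohen's *d* is defined as the post-minus-pre mean difference divided by
the global standard deviation of the rate during the run (not a pooled
window s.d.), with the conventional 0.2/0.5/0.8 small/medium/large
reading.

## The synthetic-data generator

`synth_video()` emulates a patch of skin: a seeded smooth reflectance
texture, multiplied by `1 + a·w_c·sin φ(t)` on the pixels carrying the
pulse, where `φ` integrates the instantaneous rate profile. Modulation is
multiplicative because the physical signal is a reflectance change;
amplitude defaults to 1% of intensity, at the upper end of facial
pulsatility, with i.i.d. Gaussian sensor noise (sd 0.01) and optional
integer-pixel whole-frame jitter as a head-micro-motion proxy. RGB
channels are modulated with weights (0.5, 1.0, 0.7) mimicking the stronger
green-band pulsatility; IR uses a single channel. `synth_ecg()` emits a
Mexican-hat QRS-like pulse (~80 ms support) at every integer crossing of
the same phase, at 2 kHz by default. `synth_session()` pairs the two on
one rate profile, optionally stepping the rate at event onsets.
`synth_hr_session()` generates rate series directly (baseline + smoothed
Gaussian fluctuation, correlation time 2 s) for calibrating the
event statistics at scale.

What the generator does **not** emulate: photorealistic skin, hemodynamic
waveform shape (dicrotic notch), sub-pixel motion, illumination drift,
compression artifacts, or occlusion. Passing tests on this generator
therefore demonstrate the correctness of the signal path — gain, band
selection, ridge tracking, statistics — not robustness to every nuisance
of real recordings; on real video, ROI placement and motion remain the
dominant failure modes.

## Numerical choices and degenerate inputs

- Intensities are `[0, 1]` floats; 8-bit sources divide by 255. Magnified
  clips keep unclipped values internally (so linearity holds exactly) and
  clip only on export.
- Frame-timing jitter is regularized by nearest-frame selection (ties to
  the earlier frame), not interpolation, so raw sensor values survive to
  the magnification stage.
- Pixel rectangles are 0-based half-open; all-tied pixel rankings resolve
  in (row, col) order, and tied wavelet maxima resolve to the lower
  frequency — every tie in the pipeline is deterministic.
- An all-zero wavelet column yields a flagged-invalid sample rather than
  an arbitrary frequency.
- A clip shorter than three cycles of the band's low edge is rejected.
- All generators draw from a private RNG stream (the caller's `.Random.seed`
  is saved and restored), so a single top-level seed makes every pipeline
  output bit-identical across runs.

## Problem sizes used by the checks

The packaged property checks run the constant-rate recovery on 60 s,
30 fps, 64×64 clips (RGB and IR); drift tracking on a 120 s, 48×48 IR clip
sweeping 100–140 BPM; coherence validation on 120 s paired sessions with a
wandering rate (s.d. 6 BPM, correlation time 15 s); the spatial map on
80×80 frames, 45 s at 20 fps, 10×10 grid — a session must span at least
two smoothing windows, or the running-averaged rate is nearly featureless
and coherence against ECG discriminates on noise; and the statistics calibration
on 200 null plus 100 effect sessions of 30 trials. These sizes are the
package's own choice of a desk-scale experiment: large enough that every
stage operates in its intended regime, small enough to re-run routinely.

## Known limitations

- No automatic face or ROI detection; the rectangle is user-supplied.
- Video input is a directory of PNG frames (with optional timestamp
  sidecar); container formats should be exploded to frames first
  (e.g. `ffmpeg -i in.mp4 frame_%06d.png`).
- Not real-time: the ideal filter and the CWT are whole-sequence
  operations.
- Beat-to-beat intervals and heart-rate variability are out of scope for
  the video path; the wavelet ridge estimates rate, not beat times.
- The coherence summary's absolute value depends on the frequency range
  and smoothing span; compare it against the packaged surrogate null, not
  across differently configured runs.
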