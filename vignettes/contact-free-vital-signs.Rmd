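---
title: "Contact-free vital signs from video: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-free vital signs from video: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovivitals)
```

# Problem

Measuring heart rate, respiration rate and body temperature in cattle
normally requires attaching sensors, which is laborious and itself a
stressor. This package implements a contact-free alternative: the vital
signs are read out of ordinary RGB video, non-radiometric infrared video and
radiometric thermal imagery, with a feature tracker keeping the measurement
region locked onto the moving animal. A statistics module quantifies
agreement between these remote estimates and invasive references, and a
fixture module generates seeded synthetic recordings with exact ground truth
so every stage can be validated numerically.

# Model and pipeline

## Region tracking (KLT with ROI reconstruction)

A region of interest (ROI: eye area, forehead, face, ear base or nose) is
delineated on the first frame. Characteristic points inside it are proposed
by one of six detectors — minimum eigenvalue (Shi–Tomasi), Harris, FAST,
BRISK-style multi-scale FAST, a determinant-of-Hessian blob detector in the
SURF family, and a HOG-cell energy detector — and the detector that yields
the most points on the first frame is selected automatically
(`select_detector()`). Points are propagated frame to frame by a pyramidal
Kanade–Lucas–Tomasi tracker (`propagate_points()`, implemented in C++):
3 pyramid levels, a 31×31 template window (clamped at coarse levels),
iterative Lucas–Kanade refinement to 0.01 px, and forward–backward
verification that drops any point whose reverse track misses its origin by
more than 2 px.

After each propagation the ROI is *reconstructed* (`reconstruct_roi()`): if
the ratio of surviving points to the previous count is **strictly greater
than 0.70**, the ROI becomes the bounding box of the survivors padded by 5%
of its diagonal, with a binary mask excluding everything outside; at exactly
0.70 or below, the previous ROI is retained, the detector is re-run inside
it, and after 15 consecutive rejections the target is declared lost.
Accuracy is reported as the percentage of correctly tracked frames to one
decimal (`tracking_accuracy()`); against synthetic ground truth a frame
counts as correct when the tracked and true boxes overlap with IoU ≥ 0.5.

The direction of the refresh ratio (survivors over previous count) and the
two correctness modes (IoU against ground truth when available, otherwise
"not lost and the last refresh-or-retain kept at least one point") are
deliberate resolutions of ambiguities in the underlying method description;
both are pinned by tests.

## Heart rate (rPPG on the green channel)

Cardiac pulsation modulates skin color most strongly in the green channel.
`extract_green_signal()` averages the green channel over the tracked
(masked) ROI per frame; frames lost by the tracker are filled by linear
interpolation and flagged. The signal is mean-detrended and band-pass
filtered with a zero-phase second-order Butterworth over 45–240 BPM
(`bandpass_filter()`); the band brackets published bovine heart-rate ranges
with margin, and zero-phase (forward–backward) application squares the
magnitude response while preserving peak timing. `estimate_hr_series()`
then analyses Hann-tapered 10 s windows stepped exactly every 0.5 s; each
window is zero-padded so FFT bins are at most 0.5 BPM apart and the dominant
in-band peak, refined by parabolic interpolation, gives the estimate. A
window is flagged low-confidence when its peak-to-median spectral ratio
falls below 2 or it overlaps an interpolated gap longer than one second.

## Respiration rate (infrared nostril intensity)

Airflow modulates nostril-area intensity in (non-radiometric) IR video.
`extract_intensity_signal()` yields the ROI-mean per frame;
`count_breaths()` removes slow drift with a 5 s moving median
(reflect-padded so the ends are unbiased), low-pass filters at the upper
plausible rate (default 120 breaths/min, zero-phase second-order
Butterworth), and counts peaks spaced at least `60 / max_rr` seconds apart
with prominence at least half the processed signal's inter-quartile range.
The rate is `cycles × 60 / window length`; a counting (rather than
spectral) estimator keeps short windows exact, and the prominence rule
scales with the signal so the count is invariant to affine intensity
changes.

## Temperature (radiometric thermal imagery)

`read_radiometric_pair()` reads per-pixel temperature rasters stored as
32-bit float multi-page TIFF (normalised to [0, 1] with the offset/scale
recorded in a JSON sidecar, since float TIFF storage requires unit range)
plus metadata; emissivity defaults to 0.985, typical for mammalian skin,
when unspecified. `extract_roi_temperature()` computes mean, maximum,
minimum and sample SD over exactly the masked ROI pixels. For downstream
series the eye area is represented by its maximum (the ocular-thermography
convention: the hottest spot tracks core temperature best) and diffuse
regions by their mean; `summarize_temperature_series()` averages per minute
(half-open bins `[60k, 60(k+1))`) or per handling period given explicit
half-open time bounds.

## Method agreement

`paired_measurements()` holds invasive/remote pairs keyed by animal,
handling period and minute. Normality is checked with the Anderson–Darling
test (n ≥ 8), correlation with Pearson's r and its two-sided t-transform
p-value, calibration with an ordinary least-squares fit of invasive on
remote, and bias as mean ± sample SD of invasive − remote. Animals whose
reference heart-rate series has sample SD strictly above 20 bpm are
excluded (`exclude_by_sd()`). `aggregate_pairs()` averages invasive and
remote independently within `(animal, period)` or `(animal, period,
minute)` cells before analysis — minutes are nested inside periods, so the
minute-level cells carry the period key too — and per-animal correlation
coefficients are summarised as mean ± SD with range and worst p-value
(`summarize_correlations()`).

# Synthetic fixtures and their realism

All generators (`make_ppg_video()`, `make_breath_video()`,
`make_thermal_sequence()`, `make_tracking_sequence()`,
`make_paired_series()`) are pure functions of their parameters and a seed.
Texture is a field of Gaussian blobs rendered analytically, so sub-pixel
motion is exact and gradients are smooth — ideal for verifying tracker
accuracy against a closed-form trajectory. The PPG patch carries a 5-unit
sinusoidal green modulation on a 100-unit baseline and can wander on a
circular path at a commanded speed; the breath patch modulates at the
commanded respiratory frequency; the thermal scene shows eye-area pixels at
core − 1.1 °C and ear-base pixels at core − 3.1 °C with Gaussian noise,
alongside a logger that samples core exactly every 60 s.

These fixtures are deliberately idealised: sinusoidal physiology, rigid
motion, Gaussian noise and a flat background. They validate the numerics —
filter gains, peak counting, tracking geometry, statistical formulas — not
field performance. One subtlety they do expose: when comparing minute-mean
remote temperatures to a logger that samples instantaneously at minute
starts, a rising core trajectory biases the difference by slope × 30 s,
which is a property of the comparison design, not of the estimator.

# Numerical choices

- **31×31 KLT window, 3 levels**: large enough to lock onto blob texture,
  with coarse levels absorbing multi-pixel motion; forward–backward checking
  at 2 px removes drifting points before they corrupt the ROI.
- **5% diagonal padding** on refreshed ROIs keeps the box from shrinking
  toward the point cloud's convex hull over repeated refreshes.
- **45–240 BPM band, 10 s window, 0.5 s hop**: the window gives 6 BPM
  native resolution, zero-padding to ≤ 0.5 BPM bins plus parabolic peak
  refinement recovers tones to well under 0.5 BPM; the hop fixes the
  reporting cadence exactly (0.5 is a binary fraction, so the grid is
  float-exact).
- **Zero-phase filtering with odd-reflection padding** suppresses the edge
  transients `filtfilt` would otherwise inject into short clips.
- **Prominence ≥ 0.5 × IQR** for breath peaks rejects noise ripples without
  an absolute threshold that would break amplitude invariance.
- **Strict inequalities** at the documented boundaries: refresh only above
  0.70, exclusion only above 20 bpm SD.

Problem sizes in the tests and acceptance script (clip lengths, frame
sizes, rate grids) are the package's own validation choices, scaled to run
on one CPU in minutes.

# Limitations

The package validates computations, not animals: no claim is made here
about field accuracy on real cattle, where illumination, occlusion,
non-rigid motion and physiological variability dominate. The HR estimator
assumes a quasi-stationary rate within each 10 s window; the RR counter
assumes at least ~2 cycles per window (hence the 10 s minimum and the
5–120 breaths/min band); thermal accuracy is bounded by the radiometric
calibration and emissivity assumption of the source imagery. MP4 decoding
is out of scope — recordings are exchanged as PNG frame directories or
float TIFF stacks.
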