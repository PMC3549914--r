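---
title: "Quantifying zebrafish cardiodynamics from fluorescence time-lapse stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zebrafish cardiodynamics from fluorescence time-lapse stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioscreen)
```

## The measurement problem

A 5-dpf zebrafish larva has a transparent body and, in lines expressing an
endothelial fluorophore, a heart that images as a bright chamber on a dark
background. Filming the ventricle through one optical plane at high speed
yields a time series of cross-sectional areas; cardiac physiology, however,
is expressed in volumes: stroke volume (SV), heart rate (HR), cardiac
output (CO = SV x HR) and ejection fraction (EF = SV / end-diastolic
volume). `cardioscreen` closes that gap in three stages — segment, convert,
analyse — and ships a synthetic-data generator that provides exact ground
truth for every stage, so the whole chain is testable without microscope
data.

## Ventricle detection

Each frame is thresholded to an inclusive intensity band, the surviving
pixels are labelled into 4-connected components, interior holes are filled,
and components smaller than 1000 µm² are discarded. Where several objects
survive, the largest is taken (the ventricle dominates a well-framed field
of view); frames with no survivor are flagged and filled by linear
interpolation, and a trace with more than `max_missing_fraction` (default
10%) such frames is rejected outright rather than silently patched.

Three of these choices are genuinely open and are fixed here by
convention, stated so results are reproducible bit for bit:

* **Connectivity** is 4-connected. It is the conservative choice (it never
  merges objects that 8-connectivity would separate) and makes the
  exhaustive flood-fill oracle in the test suite exact.
* **Gap filling** means morphological filling of interior background
  regions fully enclosed by an object, nothing more.
* **Intensity bands are native units.** No rescaling or normalisation is
  applied to pixel values, so the same band always selects the same pixels.

The intensity band itself remains a user input: it is an empirical property
of each imaging configuration and no automatic band-selection rule is
implied by the detection model.

## From area to volume: the prolate-spheroid calibration

The ventricle is treated as a prolate spheroid, V = (4/3) pi x y z. The
in-plane semi-axes x and y are never needed individually: they enter only
through the measured cross-section A = pi x y, giving

V = (4/3) A C,

where C is the semi-axis along the optical (z) axis. C is not observable in
a single-plane movie, so it is calibrated once on chemically arrested
hearts: a full z-stack gives each heart's true volume, the mid-stack slice
its area, C follows by algebraic inversion (C = 3V / 4A), and an ordinary
least-squares regression of C on A (free intercept) yields a linear model
C(A) = slope x A + intercept. The reference calibration on five arrested
5-dpf hearts is C = 6.8e-4 x A + 46 (µm, µm²); `fit_calibration` recovers
those coefficients to machine precision from noiseless pairs on that line.

The model records the calibrated area range (observed areas ±20%).
Converting areas outside it warns rather than errors: mild extrapolation is
inherent to applying an arrested-heart calibration to a beating heart, and
a hard failure would be worse than a visible caution.

## Two analysis methods and a manual reference

**Fourier method.** The volume trace is mean-subtracted, multiplied by a
Tukey tapered-cosine window with tapered fraction r = 0.5, and discrete
Fourier transformed. One-sided magnitudes are divided by the sum of the
window samples — a single normalisation that corrects both for trace length
and for the window's coherent gain — and all bins with a conjugate partner
are doubled. Under this normalisation a sinusoid sitting on a bin reads its
true amplitude, which pins down the convention the package uses (the
doubling of the spectral peak to get peak-to-peak volume is then exact by
construction: SV = 2 x peak amplitude, HR = peak frequency). Mean diastolic
and systolic volumes are placed symmetrically around the trace mean at
±SV/2. The spectral peak is an argmax over a physiological band, 0.5–5 Hz
by default; without the band restriction, residual drift leakage near DC
can win the argmax on quiet traces. No sub-bin interpolation is applied:
at the default 8-s acquisition the bin width is 1/8 s = 0.125 Hz, and HR is
reported at that resolution.

**Segmentation method.** HR is estimated from the same spectrum, the trace
is cut into consecutive non-overlapping segments of 110% of the period
(long enough that every segment contains a full systole and diastole), and
the per-segment global maxima and minima are averaged to give mean
diastolic and systolic volume; SV is their difference. Segments start at
the first sample; a trailing remainder at least one period long is kept as
a short final segment, anything shorter is discarded — its samples are
dropped, not merged into the previous segment, so a partial cycle can
never bias the last extremum pair.

**Manual reference.** Emulating how a human reads the waveform, every peak
and trough with topographic prominence of at least a set fraction of the
trace's global range (default 0.5; 0.25 is more appropriate for erratic
traces with variable beat amplitudes) is marked; SV is mean(peaks) −
mean(troughs) and HR is the beat count over the first-to-last-peak
interval. This is the reference both automated methods are validated
against in `compare_methods`.

**Why the methods differ, and by how much.** The Fourier amplitude reflects
only the fundamental, so on non-sinusoidal waveforms it reads low relative
to the true peak-to-peak change — for a waveform with a second harmonic at
20–50% of the fundamental, systematically below the segmentation estimate.
Conversely, segmentation takes sampled extrema: at 22.75 frames/s and
2.5 Hz the sampled crest undershoots the true crest by up to
SV(1 − cos(pi HR / fs))/2, about 3% of the half-amplitude, so even on a
noiseless sinusoid the segmentation SV sits 1–2% below truth while the
Fourier SV is exact to within 0.01%. For *near*-sinusoidal waveforms
(harmonics under ~15%) these two effects are the same size, and neither
method dominates; the package therefore treats "Fourier reads lower than
segmentation" as a property of genuinely harmonic-rich waveforms only.
Both effects are properties of the estimators, not bugs; the EF denominator
is the mean diastolic volume (the end-diastolic analogue), the identity
EF = SV / EDV holding exactly on every output.

## The synthetic-data generator

`generate_volume_trace` builds a per-beat schedule and evaluates a
phase-locked harmonic waveform on the acquisition grid:

* defaults of 22.75 frames/s and 8 s mirror the acquisition settings the
  analysis constants (0.125 Hz bins, ~20 beats) are designed around;
  baseline volume 7e5 µm³ and SV 2e5 µm³ sit on the scale implied by the
  reference calibration (a 10,000 µm² ventricle maps to 704,000 µm³);
* *erratic* rhythms multiply each beat's period and amplitude by lognormal
  factors with sigma = `erratic_jitter` and unit mean — a stand-in chosen
  for its two independent, interpretable knobs, not an inferred model of
  any particular arrhythmia;
* harmonics are integer multiples of the beat frequency, phase-locked so
  the waveform stays continuous across beat boundaries;
* ground truth is computed from a dense (512 points/beat) evaluation of the
  noiseless, drift-free waveform, averaging per-beat extrema over beats
  fully inside the window. Drift and noise are treated as nuisance terms of
  the measurement, not part of the true cardiac state.

`render_frame_stack` draws, per frame, one filled ellipse whose area is the
exact algebraic inverse of the prolate-spheroid conversion at that frame's
volume, with a fixed in-plane aspect ratio (both radii scale with
sqrt(area), since only the product of the in-plane radii is constrained by
the model). What the renderer deliberately does *not* emulate: optical
blur, photon noise statistics, a second chamber, fish motion, or partial
occlusion. Passing the render→detect→convert→analyse round trip therefore
demonstrates the correctness of the arithmetic chain under ideal contrast,
not robustness to real microscope pathology; the detection tolerance it
does establish (areas within 2% at 1 µm/px) is pure pixelation error.

For the plate-screening module, synthetic wells draw each image's pixels
i.i.d. Gaussian around the well mean, which is exactly the regime in which
the standard error of the per-well mean must fall as 1/sqrt(images) — the
property used to choose slice counts in a screen. The z-range convention is
the span between first and last slice centres, (n − 1) x spacing: the only
reading under which 6 slices at 50 µm span 250 µm.

## Numerical choices and degenerate inputs

* A flat (or near-flat) trace has no dominant spectral peak; the spectrum
  functions raise "no dominant frequency" rather than returning SV = 0, so
  a dead heart is never silently reported as a zero-output one.
* Traces shorter than two periods of the lowest band frequency are
  rejected before any FFT is taken.
* `fit_calibration` requires two pairs with distinct areas; the slope is
  otherwise unidentifiable and the error says so.
* Trace CSVs are written with 17 significant digits, making the
  read/write round trip bitwise lossless; TIFF stacks are 16-bit, so their
  round trip is exact to 1/65535.
* All RNG flows through explicit seeds; every generator is
  bitwise-reproducible under a fixed seed.

## Problem sizes

The validation suites run at the scale the defaults describe: 182-sample
traces (8 s at 22.75 frames/s), 160x160 px rendered stacks at 1 µm/px,
cohorts of 20 traces for method agreement, 100 harmonic-rich waveforms for
the Fourier-vs-segmentation inequality, 50 noisy traces for SV recovery
(median error under 5% at 5% additive noise), and 200 replicate synthetic
wells for the SEM-scaling law. These sizes give stable statistics for each
property while keeping a full run of the suite inside a coffee break.

## Known limitations

The calibration is population-level: a single C(A) line is applied to every
fish, and calibration uncertainty is not propagated into SV or CO. The
detection model assumes one dominant bright object per frame — atrium and
ventricle are disambiguated only by the size rule and selection rule, not
by tracking. HR resolution is one spectral bin (0.125 Hz at 8 s).
Arrhythmia indices beyond the erratic-waveform comparison (beat-to-beat
variability, rhythmicity spectra) are out of scope, as are group-level
inferential statistics, for which standard tools apply downstream.
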