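# cardioscreen

Automated quantification of larval zebrafish cardiac function from
single-channel fluorescence time-lapse microscopy, plus the acquisition
planning and per-well fluorescence summaries used in high-content
well-plate screens.

Transgenic zebrafish larvae with a fluorescent heart make cardiac
physiology visible through one optical plane: a high-speed movie of the
beating ventricle is a time series of bright cross-sections. `cardioscreen`
turns such a movie into the standard inotropic readouts:

1. **Detection** — each frame is thresholded to an intensity band,
   4-connected components are labelled, interior holes filled, and objects
   under 1000 µm² discarded; the surviving object's area gives an
   area-vs-time trace A(t).
2. **Volumetrics** — modelling the ventricle as a prolate spheroid,
   V = (4/3)·A·C, where the optical-axis radius C is predicted from area by
   a linear calibration C(A) = slope·A + intercept fitted on arrested
   hearts (reference line: C = 6.8×10⁻⁴·A + 46).
3. **Cardiodynamics** — from the volume trace V(t), stroke volume (SV),
   heart rate (HR), cardiac output (CO = SV·HR) and ejection fraction
   (EF = SV/EDV) are estimated two ways: a pure frequency-domain method
   (Tukey-windowed FFT, r = 0.5; SV = 2 × normalised spectral peak, HR =
   peak frequency) and a combined frequency/time-domain method (the trace
   is cut into segments of 110% of the estimated period and per-segment
   extrema are averaged). A manual-style peak/trough reference and a
   method-comparison table (`compare_methods`) validate them against each
   other.
4. **Plate screening** — acquisition planning (stacks × slices × spacing),
   per-well mean fluorescence with SEM over image means, group summaries
   with zero-well exclusion, and a linear dose–response fit.

A synthetic-data generator (waveforms with harmonics, noise, drift and
erratic beats; rendered ellipsoidal frame stacks; calibration pair sets;
well-plate image sets) provides exact ground truth for every stage.

## Worked example

Simulate an 8-s acquisition at 22.75 frames/s of a heart with true
SV = 2×10⁵ µm³ beating at 2.5 Hz, render it, and run the full chain:

```r
library(cardioscreen)

sim      <- generate_volume_trace(waveform_params(noise_sd = 5e3, seed = 42))
rendered <- render_frame_stack(sim$trace, render_params(seed = 43))
at       <- detect_area_trace(rendered$stack, detection_params(c(0.45, 1.0)))
fit      <- fit_calibration(
              generate_calibration_set(5, c(5e3, 1.5e4),
                                       calibration_model(6.8e-4, 46)))
vt       <- convert_trace(at, fit, warn_extrapolation = FALSE)
segmentation_metrics(vt)
#> cardiac_metrics [segmentation]
#>   SV  1.967e+05 um^3   HR  2.5 Hz (150 bpm)
#>   CO  4.918e+05 um^3/s (29.51 nL/min)   EF  0.2462
#>   diastolic 7.9896e+05 / systolic 6.0224e+05 um^3
fourier_metrics(vt)
#> cardiac_metrics [fourier]
#>   SV  1.992e+05 um^3   HR  2.5 Hz (150 bpm)
#>   CO  4.981e+05 um^3/s (29.89 nL/min)   EF  0.2492
#>   diastolic 7.9944e+05 / systolic 6.002e+05 um^3
```

Both methods recover the constructed truth (SV 2×10⁵ µm³, HR 2.5 Hz,
EF 0.25) to within ~2%: the full detection→calibration→conversion→analysis
chain loses almost nothing on clean synthetic data. The Fourier estimate
sits slightly above the segmentation one here because segmentation takes
sampled extrema, which undershoot the true crests at finite frame rate;
on strongly non-sinusoidal waveforms the ordering reverses (see the
methods vignette).

A command-line front end over the same functions lives at
`inst/cli/cardioscreen.R`:

```sh
Rscript inst/cli/cardioscreen.R simulate --out demo --seed 3
Rscript inst/cli/cardioscreen.R detect --stack demo/stack.tif --meta demo/stack.json \
    --lo 0.45 --hi 1.0 --out demo/area.csv
Rscript inst/cli/cardioscreen.R analyze --trace demo/volume.csv --method all --out demo/metrics.json
```

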