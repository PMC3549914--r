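#' Parameters for the synthetic cardiac waveform generator
#'
#' Defaults describe a healthy 5-dpf larva imaged the way the analysis
#' expects: ~2.5 Hz beat, 22.75 frames/s for 8 s. Volumes are on the scale
#' set by the arrested-heart calibration (a 10,000 um^2 ventricle maps to
#' about 7e5 um^3).
#'
#' @param baseline_volume mean ventricular volume (um^3).
#' @param stroke_volume true peak-to-peak volume change of the fundamental
#'   (um^3); with harmonics the realised peak-to-peak can exceed it.
#' @param heart_rate beat frequency (Hz).
#' @param harmonic_amplitudes relative amplitudes of harmonics 2..k as
#'   fractions of the fundamental amplitude.
#' @param noise_sd additive Gaussian measurement noise (um^3).
#' @param drift_rate linear baseline drift (um^3/s).
#' @param erratic_jitter lognormal sigma of the per-beat period and amplitude
#'   multipliers (0 = perfectly regular).
#' @param duration acquisition length (s).
#' @param sample_rate frame rate (frames/s); must exceed 2 x `heart_rate`.
#' @param seed integer RNG seed, or `NULL` to use the current stream.
#' @return a validated list of class `waveform_params`.
#' @export
waveform_params <- function(baseline_volume = 7e5, stroke_volume = 2e5,
                            heart_rate = 2.5, harmonic_amplitudes = numeric(0),
                            noise_sd = 0, drift_rate = 0, erratic_jitter = 0,
                            duration = 8, sample_rate = 22.75, seed = NULL) {
  p <- list(baseline_volume = baseline_volume, stroke_volume = stroke_volume,
            heart_rate = heart_rate,
            harmonic_amplitudes = as.numeric(harmonic_amplitudes),
            noise_sd = noise_sd, drift_rate = drift_rate,
            erratic_jitter = erratic_jitter, duration = duration,
            sample_rate = sample_rate, seed = seed)
  if (p$stroke_volume < 0) stop("waveform_params: stroke_volume must be >= 0")
  if (p$heart_rate <= 0) stop("waveform_params: heart_rate must be > 0")
  if (p$duration <= 0 || p$sample_rate <= 0)
    stop("waveform_params: duration and sample_rate must be > 0")
  if (p$sample_rate <= 2 * p$heart_rate)
    stop(sprintf(
      "waveform_params: sample_rate (%.4g fps) must exceed twice the heart rate (%.4g Hz) to satisfy Nyquist",
      p$sample_rate, p$heart_rate))
  if (p$baseline_volume - p$stroke_volume / 2 <= 0)
    stop("waveform_params: baseline_volume - stroke_volume/2 must stay positive")
  if (p$noise_sd < 0 || p$erratic_jitter < 0)
    stop("waveform_params: noise_sd and erratic_jitter must be >= 0")
  class(p) <- "waveform_params"
  p
}

# Beat schedule covering [0, duration]: start time, period and amplitude
# multiplier per beat. Jitter multiplies both by lognormal factors with
# meanlog = -sigma^2/2 so their expectation stays 1.
beat_schedule <- function(params) {
  mean_period <- 1 / params$heart_rate
  sigma <- params$erratic_jitter
  periods <- numeric(0)
  amps <- numeric(0)
  total <- 0
  while (total < params$duration) {
    mult <- if (sigma > 0)
      stats::rlnorm(2, meanlog = -sigma^2 / 2, sdlog = sigma) else c(1, 1)
    periods <- c(periods, mean_period * mult[1])
    amps <- c(amps, mult[2])
    total <- total + mean_period * mult[1]
  }
  data.frame(start = cumsum(c(0, periods[-length(periods)])),
             period = periods, amp_mult = amps)
}

# Noiseless, drift-free waveform at times t for a given beat schedule.
# Within beat k the phase runs 0..2pi; harmonics are phase-locked sines, so
# the waveform is continuous across beat boundaries.
eval_waveform <- function(t, params, beats) {
  k <- findInterval(t, beats$start)
  k[k < 1] <- 1
  phase <- 2 * pi * (t - beats$start[k]) / beats$period[k]
  fund <- (params$stroke_volume / 2) * beats$amp_mult[k]
  v <- sin(phase)
  h <- params$harmonic_amplitudes
  for (j in seq_along(h)) v <- v + h[j] * sin((j + 1) * phase)
  params$baseline_volume + fund * v
}

# Ground-truth metrics from the beat schedule: per-beat extrema of the
# noiseless, drift-free waveform, averaged over beats fully inside the
# acquisition window (dense evaluation, 512 points per beat).
truth_from_schedule <- function(params, beats) {
  full <- beats$start + beats$period <= params$duration + 1e-12
  if (!any(full)) full[1] <- TRUE
  idx <- which(full)
  maxima <- numeric(length(idx))
  minima <- numeric(length(idx))
  for (m in seq_along(idx)) {
    k <- idx[m]
    tt <- beats$start[k] + beats$period[k] * seq(0, 1, length.out = 512)
    vv <- eval_waveform(tt, params, beats)
    maxima[m] <- max(vv)
    minima[m] <- min(vv)
  }
  mean_dia <- mean(maxima)
  mean_sys <- mean(minima)
  cardiac_metrics(
    stroke_volume = mean_dia - mean_sys,
    heart_rate_hz = 1 / mean(beats$period[idx]),
    mean_diastolic_volume = mean_dia, mean_systolic_volume = mean_sys,
    method = "truth", n_segments_or_beats = length(idx))
}

#' Generate a synthetic ventricular volume trace with known ground truth
#'
#' Builds a per-beat schedule (regular, or jittered for erratic rhythms),
#' evaluates a phase-locked harmonic waveform on the acquisition time grid,
#' and adds linear drift and Gaussian noise. Ground-truth metrics are
#' computed from the noiseless, drift-free waveform: per-beat maxima/minima
#' give the true mean diastolic and systolic volumes, their difference the
#' true stroke volume, and the mean beat period the true heart rate.
#'
#' @param params a [waveform_params] object.
#' @return a list with `trace` (a [volume_trace]), `truth` (a
#'   [cardiac_metrics] with `method = "truth"`), and `beats` (the beat
#'   schedule: start time, period, amplitude multiplier per beat).
#' @examples
#' sim <- generate_volume_trace(waveform_params(seed = 1))
#' sim$truth
#' @export
generate_volume_trace <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  with_seed(params$seed, {
    n <- floor(params$duration * params$sample_rate)
    t <- (seq_len(n) - 1) / params$sample_rate
    beats <- beat_schedule(params)
    clean <- eval_waveform(t, params, beats)
    if (any(clean + params$drift_rate * t <= 0))
      stop("generate_volume_trace: noiseless construction reaches non-positive volume; increase baseline_volume")
    v <- clean + params$drift_rate * t
    if (params$noise_sd > 0) v <- v + stats::rnorm(n, 0, params$noise_sd)
    v <- pmax(v, .Machine$double.eps)
    list(trace = volume_trace(v, sample_rate = params$sample_rate, time = t),
         truth = truth_from_schedule(params, beats),
         beats = beats)
  })
}

#' Rendering parameters for synthetic fluorescence frame stacks
#'
#' Describes how a volume trace is turned into bright-ellipse-on-dark
#' frames: the calibration maps each frame's volume back to a target
#' cross-sectional area, and an axis-aligned filled ellipse with that area
#' (fixed aspect ratio, both radii scaling with sqrt(area)) is drawn at the
#' image centre. Ventricle and background intensity ranges must be disjoint
#' so that threshold detection is well posed.
#'
#' @param pixel_size um per pixel.
#' @param image_shape integer c(rows, cols).
#' @param ventricle_intensity_range c(lo, hi) in \[0, 1\], above background.
#' @param background_intensity_range c(lo, hi) in \[0, 1\].
#' @param aspect_ratio x-radius / y-radius of the rendered ellipse.
#' @param calibration [calibration_model] mapping area to C radius.
#' @param seed integer RNG seed for the intensity noise, or `NULL`.
#' @return a validated list of class `render_params`.
#' @export
render_params <- function(pixel_size = 1, image_shape = c(160, 160),
                          ventricle_intensity_range = c(0.7, 0.9),
                          background_intensity_range = c(0.05, 0.2),
                          aspect_ratio = 1.3,
                          calibration = calibration_model(6.8e-4, 46),
                          seed = NULL) {
  if (pixel_size <= 0) stop("render_params: pixel_size must be > 0")
  if (aspect_ratio <= 0) stop("render_params: aspect_ratio must be > 0")
  v <- ventricle_intensity_range
  b <- background_intensity_range
  stopifnot(length(v) == 2, length(b) == 2, v[1] < v[2] || v[1] == v[2],
            b[1] <= b[2])
  if (b[2] >= v[1])
    stop("render_params: ventricle and background intensity ranges must be disjoint (ventricle above background)")
  structure(
    list(pixel_size = pixel_size, image_shape = as.integer(image_shape),
         ventricle_intensity_range = v, background_intensity_range = b,
         aspect_ratio = aspect_ratio, calibration = calibration, seed = seed),
    class = "render_params")
}

#' Render a volume trace as a synthetic fluorescence frame stack
#'
#' Each frame contains one filled ellipse whose area (in um^2) is the
#' inverse prolate-spheroid image of that frame's volume under the rendering
#' calibration, so detection followed by [convert_trace] with the same
#' calibration recovers the input trace up to pixelation.
#'
#' @param trace a [volume_trace].
#' @param rp a [render_params] object.
#' @return a list with `stack` (a [frame_stack]) and `true_area` (per-frame
#'   target area in um^2, for oracle tests).
#' @export
render_frame_stack <- function(trace, rp) {
  stopifnot(inherits(trace, "volume_trace"), inherits(rp, "render_params"))
  area_um2 <- volume_to_area(trace$volume, rp$calibration)
  area_px <- area_um2 / rp$pixel_size^2
  rx <- sqrt(area_px * rp$aspect_ratio / pi)  # column semi-axis, px
  ry <- sqrt(area_px / (rp$aspect_ratio * pi))
  nr <- rp$image_shape[1]
  nc <- rp$image_shape[2]
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  too_big <- which(rx > cx - 1.5 | ry > cy - 1.5)
  if (length(too_big) > 0)
    stop(sprintf(
      "render_frame_stack: ellipse exceeds the %dx%d frame at frame %d (area %.5g um^2); enlarge image_shape",
      nr, nc, too_big[1], area_um2[too_big[1]]))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  with_seed(rp$seed, {
    frames <- lapply(seq_along(area_px), function(i) {
      inside <- ((cols - cx) / rx[i])^2 + ((rows - cy) / ry[i])^2 <= 1
      f <- matrix(stats::runif(nr * nc, rp$background_intensity_range[1],
                               rp$background_intensity_range[2]), nr, nc)
      n_in <- sum(inside)
      if (n_in > 0)
        f[inside] <- stats::runif(n_in, rp$ventricle_intensity_range[1],
                                  rp$ventricle_intensity_range[2])
      f
    })
    list(stack = frame_stack(frames, pixel_size = rp$pixel_size,
                             frame_rate = trace$sample_rate),
         true_area = area_um2)
  })
}

#' Generate synthetic arrested-heart calibration pairs
#'
#' Areas are evenly spaced over `area_range`; for each, the C radius is
#' drawn from the generating model plus Gaussian noise and the volume set to
#' V = (4/3) A C. With zero noise the pairs lie exactly on the model, so
#' [fit_calibration] recovers slope and intercept to machine precision.
#'
#' @param n number of pairs (>= 2).
#' @param area_range c(min, max) areas in um^2, positive.
#' @param model generating [calibration_model].
#' @param noise_sd_C Gaussian noise on the C radius (um).
#' @param seed integer RNG seed, or `NULL`.
#' @return data frame with columns `area_um2`, `volume_um3`.
#' @export
generate_calibration_set <- function(n, area_range, model, noise_sd_C = 0,
                                     seed = NULL) {
  if (n < 2) stop("generate_calibration_set: need n >= 2 (a line needs two points)")
  stopifnot(length(area_range) == 2, all(area_range > 0),
            inherits(model, "calibration_model"), noise_sd_C >= 0)
  a <- seq(area_range[1], area_range[2], length.out = n)
  with_seed(seed, {
    cc <- model$slope * a + model$intercept +
      if (noise_sd_C > 0) stats::rnorm(n, 0, noise_sd_C) else 0
    if (any(cc <= 0))
      stop("generate_calibration_set: noise drove a C radius non-positive")
    data.frame(area_um2 = a, volume_um3 = (4 / 3) * a * cc)
  })
}

#' Generate synthetic well-plate image sets
#'
#' Each well yields `images_per_well` small images whose pixels are i.i.d.
#' Gaussian around the well's mean intensity, emulating per-well fluorescence
#' readouts whose standard error shrinks as 1/sqrt(number of images).
#'
#' @param n_wells number of wells.
#' @param images_per_well images per well (>= 1).
#' @param intensity_means per-well mean intensity (length 1 or `n_wells`).
#' @param intensity_sd pixel-level Gaussian SD (same units as intensity).
#' @param seed integer RNG seed, or `NULL`.
#' @param image_shape integer c(rows, cols) of each image.
#' @return named list (one entry per well) of lists of image matrices.
#' @export
generate_wellplate_set <- function(n_wells, images_per_well, intensity_means,
                                   intensity_sd, seed = NULL,
                                   image_shape = c(8, 8)) {
  if (images_per_well < 1) stop("generate_wellplate_set: images_per_well must be >= 1")
  stopifnot(n_wells >= 1, intensity_sd >= 0)
  mu <- rep_len(intensity_means, n_wells)
  npx <- prod(image_shape)
  with_seed(seed, {
    wells <- lapply(seq_len(n_wells), function(w) {
      lapply(seq_len(images_per_well), function(i) {
        matrix(mu[w] + if (intensity_sd > 0)
          stats::rnorm(npx, 0, intensity_sd) else 0,
          image_shape[1], image_shape[2])
      })
    })
    names(wells) <- sprintf("W%02d", seq_len(n_wells))
    wells
  })
}
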