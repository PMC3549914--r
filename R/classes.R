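#' Construct an area-vs-time trace
#'
#' An `area_trace` holds the ventricular cross-sectional area measured on each
#' frame of a time-lapse acquisition, on a uniform time grid derived from the
#' frame rate. Frames where detection failed are flagged in `missing` (their
#' area has been filled by interpolation).
#'
#' @param area numeric vector, ventricular area per frame (um^2).
#' @param sample_rate frames per second.
#' @param missing logical vector flagging frames with no surviving object.
#' @param time optional explicit time grid (s); defaults to `(0:(n-1))/sample_rate`.
#' @return an object of class `area_trace` with fields `time`, `area`,
#'   `missing`, `sample_rate`, `duration`.
#' @export
area_trace <- function(area, sample_rate, missing = NULL, time = NULL) {
  n <- length(area)
  stopifnot(n >= 1, is.numeric(sample_rate), sample_rate > 0)
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  if (is.null(missing)) missing <- rep(FALSE, n)
  stopifnot(length(time) == n, length(missing) == n)
  if (any(area[!missing] <= 0))
    stop("area_trace: non-positive area at frame ",
         which(!missing & area <= 0)[1])
  structure(
    list(time = as.numeric(time), area = as.numeric(area),
         missing = as.logical(missing), sample_rate = sample_rate,
         duration = n / sample_rate),
    class = "area_trace")
}

#' Construct a volume-vs-time trace
#'
#' A `volume_trace` holds ventricular volume per frame on a uniform time grid;
#' it is the input to all cardiodynamic analyses.
#'
#' @param volume numeric vector, ventricular volume per frame (um^3).
#' @inheritParams area_trace
#' @return an object of class `volume_trace` with fields `time`, `volume`,
#'   `missing`, `sample_rate`, `duration`.
#' @export
volume_trace <- function(volume, sample_rate, missing = NULL, time = NULL) {
  n <- length(volume)
  stopifnot(n >= 1, is.numeric(sample_rate), sample_rate > 0)
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  if (is.null(missing)) missing <- rep(FALSE, n)
  stopifnot(length(time) == n, length(missing) == n)
  if (any(volume <= 0))
    stop("volume_trace: non-positive volume at frame ", which(volume <= 0)[1])
  structure(
    list(time = as.numeric(time), volume = as.numeric(volume),
         missing = as.logical(missing), sample_rate = sample_rate,
         duration = n / sample_rate),
    class = "volume_trace")
}

#' Construct a fluorescence frame stack
#'
#' Time-ordered single-channel 2-D frames with the physical metadata needed to
#' convert pixel counts to areas and frame indices to seconds.
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param pixel_size physical pixel size (um/px).
#' @param frame_rate acquisition rate (frames/s).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, frame_rate) {
  stopifnot(is.list(frames), length(frames) >= 1,
            pixel_size > 0, frame_rate > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frame_stack: all frames must share one shape")
  structure(
    list(frames = frames, pixel_size = pixel_size, frame_rate = frame_rate,
         n_frames = length(frames), shape = dims[, 1]),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames of %dx%d px, %.4g um/px, %.4g fps\n",
              x$n_frames, x$shape[1], x$shape[2], x$pixel_size, x$frame_rate))
  invisible(x)
}

#' @export
print.area_trace <- function(x, ...) {
  cat(sprintf(
    "area_trace: %d samples @ %.4g fps (%.3g s), area %.4g-%.4g um^2, %d missing\n",
    length(x$area), x$sample_rate, x$duration, min(x$area), max(x$area),
    sum(x$missing)))
  invisible(x)
}

#' @export
print.volume_trace <- function(x, ...) {
  cat(sprintf(
    "volume_trace: %d samples @ %.4g fps (%.3g s), volume %.4g-%.4g um^3\n",
    length(x$volume), x$sample_rate, x$duration, min(x$volume), max(x$volume)))
  invisible(x)
}

#' Bundle of cardiac performance metrics
#'
#' Collects the outputs of one analysis method. The fields satisfy the
#' identities CO = SV x HR and EF = SV / mean diastolic volume; heart rate and
#' cardiac output are carried in both per-second and conventional units
#' (1 nL/min = 1e6 um^3 / 60 s).
#'
#' @param stroke_volume SV (um^3): mean diastolic minus mean systolic volume.
#' @param heart_rate_hz HR (beats/s).
#' @param mean_diastolic_volume average end-diastolic (maximal) volume (um^3).
#' @param mean_systolic_volume average end-systolic (minimal) volume (um^3).
#' @param method one of `"fourier"`, `"segmentation"`, `"manual"`, `"truth"`.
#' @param n_segments_or_beats segments (segmentation) or beats (manual/truth)
#'   the estimate averaged over; `NA` for the Fourier method.
#' @return an object of class `cardiac_metrics`.
#' @export
cardiac_metrics <- function(stroke_volume, heart_rate_hz,
                            mean_diastolic_volume, mean_systolic_volume,
                            method, n_segments_or_beats = NA_integer_) {
  stopifnot(stroke_volume >= 0, heart_rate_hz > 0,
            mean_diastolic_volume > 0)
  co <- stroke_volume * heart_rate_hz
  structure(
    list(stroke_volume = stroke_volume,
         heart_rate_hz = heart_rate_hz,
         heart_rate_bpm = heart_rate_hz * 60,
         period = 1 / heart_rate_hz,
         cardiac_output = co,
         cardiac_output_nl_min = co * 60 / 1e6,
         ejection_fraction = stroke_volume / mean_diastolic_volume,
         mean_diastolic_volume = mean_diastolic_volume,
         mean_systolic_volume = mean_systolic_volume,
         method = method,
         n_segments_or_beats = n_segments_or_beats),
    class = "cardiac_metrics")
}

#' @export
print.cardiac_metrics <- function(x, ...) {
  cat(sprintf("cardiac_metrics [%s]\n", x$method))
  cat(sprintf("  SV  %.4g um^3   HR  %.4g Hz (%.4g bpm)\n",
              x$stroke_volume, x$heart_rate_hz, x$heart_rate_bpm))
  cat(sprintf("  CO  %.4g um^3/s (%.4g nL/min)   EF  %.4g\n",
              x$cardiac_output, x$cardiac_output_nl_min, x$ejection_fraction))
  cat(sprintf("  diastolic %.5g / systolic %.5g um^3\n",
              x$mean_diastolic_volume, x$mean_systolic_volume))
  invisible(x)
}

#' @export
as.data.frame.cardiac_metrics <- function(x, ...) {
  data.frame(method = x$method,
             sv_um3 = x$stroke_volume,
             hr_hz = x$heart_rate_hz,
             hr_bpm = x$heart_rate_bpm,
             co_um3_s = x$cardiac_output,
             co_nl_min = x$cardiac_output_nl_min,
             ef = x$ejection_fraction,
             mean_diastolic_um3 = x$mean_diastolic_volume,
             mean_systolic_um3 = x$mean_systolic_volume,
             n_segments = x$n_segments_or_beats,
             stringsAsFactors = FALSE)
}
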