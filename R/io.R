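#' Analysis configuration
#'
#' Gathers the fixed constants of the whole pipeline so a run is
#' reproducible from one serialisable object: Tukey taper, physiological
#' band, 110% segment factor, 1000 um^2 minimum object area, tolerated
#' missing-frame fraction, and the RNG seed.
#'
#' @param tukey_r Tukey window tapered fraction (default 0.5).
#' @param band_hz c(lo, hi) spectral peak search band (default 0.5-5 Hz).
#' @param segment_factor segment length / period (default 1.1).
#' @param min_area_um2 minimum detected object area (default 1000 um^2).
#' @param max_missing_fraction tolerated missing-frame fraction (default 0.10).
#' @param prominence_fraction manual-method peak prominence threshold.
#' @param seed integer RNG seed.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(tukey_r = 0.5, band_hz = c(0.5, 5.0),
                            segment_factor = 1.1, min_area_um2 = 1000,
                            max_missing_fraction = 0.10,
                            prominence_fraction = 0.5, seed = 1L) {
  stopifnot(segment_factor >= 1, length(band_hz) == 2, band_hz[1] < band_hz[2],
            tukey_r >= 0, tukey_r <= 1, min_area_um2 >= 0)
  structure(
    list(tukey_r = tukey_r, band_hz = as.numeric(band_hz),
         segment_factor = segment_factor, min_area_um2 = min_area_um2,
         max_missing_fraction = max_missing_fraction,
         prominence_fraction = prominence_fraction, seed = as.integer(seed)),
    class = "analysis_config")
}

#' Read or write an analysis configuration as JSON
#'
#' @param path JSON file path.
#' @param config an [analysis_config].
#' @return `read_config` returns an [analysis_config]; `write_config`
#'   returns `path` invisibly. The round trip is the identity.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, x)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

fmt_full <- function(x) {
  if (is.logical(x)) return(as.character(as.integer(x)))
  formatC(x, digits = 17, format = "g")
}

#' Write a trace to CSV at full precision
#'
#' Columns are `time_s` plus `area_um2` (area traces) or `volume_um3`
#' (volume traces), and `missing` (0/1). Values are written with 17
#' significant digits so that [read_trace] reproduces them bit for bit.
#'
#' @param trace an [area_trace] or [volume_trace].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "area_trace")) {
    df <- data.frame(time_s = fmt_full(trace$time),
                     area_um2 = fmt_full(trace$area),
                     missing = fmt_full(trace$missing))
  } else if (inherits(trace, "volume_trace")) {
    df <- data.frame(time_s = fmt_full(trace$time),
                     volume_um3 = fmt_full(trace$volume),
                     missing = fmt_full(trace$missing))
  } else stop("write_trace: not a trace object")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' The header decides the trace kind: a `area_um2` column yields an
#' [area_trace], a `volume_um3` column a [volume_trace]. The time grid must
#' be uniform; the first non-uniform row is reported otherwise.
#'
#' @param path CSV path with header `time_s,area_um2|volume_um3[,missing]`.
#' @return an [area_trace] or [volume_trace].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop("read_trace: malformed header; expected a time_s column")
  kind <- if ("area_um2" %in% names(df)) "area"
          else if ("volume_um3" %in% names(df)) "volume"
          else stop("read_trace: malformed header; expected area_um2 or volume_um3")
  t <- df$time_s
  if (length(t) < 2) stop("read_trace: need at least 2 rows")
  dt <- diff(t)
  bad <- which(abs(dt - dt[1]) > 1e-9 * max(abs(dt[1]), 1e-12) | dt <= 0)
  if (length(bad) > 0)  # file line number, header included
    stop(sprintf("read_trace: non-uniform time grid at row %d", bad[1] + 2))
  fs <- 1 / dt[1]
  miss <- if ("missing" %in% names(df)) as.logical(df$missing) else NULL
  if (kind == "area")
    area_trace(df$area_um2, sample_rate = fs, missing = miss, time = t)
  else
    volume_trace(df$volume_um3, sample_rate = fs, missing = miss, time = t)
}

#' Write or read a frame stack as multi-page TIFF plus metadata JSON
#'
#' Frames are stored as 16-bit grayscale pages (intensities are clipped to
#' \[0, 1\] on write); pixel size and frame rate go to a JSON sidecar.
#'
#' @param stack a [frame_stack].
#' @param tiff_path multi-page TIFF path.
#' @param meta_path metadata JSON path (default: TIFF path with .json).
#' @return `write_stack` returns `tiff_path` invisibly; `read_stack` a
#'   [frame_stack].
#' @export
write_stack <- function(stack, tiff_path, meta_path = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".json", tiff_path)
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, tiff_path, bits.per.sample = 16)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size, frame_rate_fps = stack$frame_rate),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_stack
#' @export
read_stack <- function(tiff_path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".json", tiff_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- tiff::readTIFF(tiff_path, all = TRUE)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f
  })
  frame_stack(frames, pixel_size = meta$pixel_size_um,
              frame_rate = meta$frame_rate_fps)
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] running")
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full simulate-detect-convert-analyze pipeline
#'
#' End-to-end check of the whole toolchain on synthetic data: generate a
#' ground-truth waveform, render it as a fluorescence stack, detect the
#' area trace, fit the calibration from synthetic arrested-heart pairs,
#' convert to volume, and analyse with all three methods. Deterministic
#' given `config$seed`; the returned bundle records the configuration and
#' its hash for provenance.
#'
#' @param config an [analysis_config].
#' @param wf a [waveform_params]; its `seed` is taken from `config` when
#'   unset.
#' @param rp a [render_params] for the synthetic stack.
#' @param calibration_pairs data frame of arrested-heart pairs; by default
#'   5 noiseless pairs generated from the rendering calibration.
#' @param verbose log each stage (default FALSE).
#' @return a list of class `pipeline_result`: `config`, `config_hash`,
#'   `truth`, `trace_volume_true`, `area_trace`, `calibration`,
#'   `volume_trace`, `metrics` (list of [cardiac_metrics] per method) and
#'   `comparison`.
#' @export
run_pipeline <- function(config = analysis_config(),
                         wf = NULL, rp = NULL,
                         calibration_pairs = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(wf))
    wf <- waveform_params(noise_sd = 5e3, seed = config$seed)
  if (is.null(wf$seed)) wf$seed <- config$seed
  if (is.null(rp))
    rp <- render_params(seed = config$seed + 1L)
  sim <- run_stage("simulate", verbose, generate_volume_trace(wf))
  rendered <- run_stage("render", verbose, render_frame_stack(sim$trace, rp))
  dp <- detection_params(
    intensity_range = c((rp$background_intensity_range[2] +
                           rp$ventricle_intensity_range[1]) / 2,
                        rp$ventricle_intensity_range[2] + 0.05),
    min_area = config$min_area_um2,
    max_missing_fraction = config$max_missing_fraction)
  atrace <- run_stage("detect", verbose, detect_area_trace(rendered$stack, dp))
  if (is.null(calibration_pairs))
    calibration_pairs <- run_stage("calibration-data", verbose,
      generate_calibration_set(5, range(atrace$area) * c(0.8, 1.2),
                               rp$calibration, noise_sd_C = 0,
                               seed = config$seed))
  calib <- run_stage("calibrate", verbose, fit_calibration(calibration_pairs))
  vtrace <- run_stage("convert", verbose,
                      convert_trace(atrace, calib, warn_extrapolation = FALSE))
  metrics <- run_stage("analyze", verbose, list(
    fourier = fourier_metrics(vtrace, config$tukey_r, config$band_hz),
    segmentation = segmentation_metrics(vtrace, config$segment_factor,
                                        config$tukey_r, config$band_hz),
    manual = manual_oracle_metrics(vtrace, config$prominence_fraction)))
  comparison <- run_stage("compare", verbose,
    compare_methods(list(run = vtrace), segment_factor = config$segment_factor,
                    tukey_r = config$tukey_r, band = config$band_hz,
                    prominence_fraction = config$prominence_fraction))
  structure(
    list(config = config, config_hash = config_hash(config),
         truth = sim$truth, trace_volume_true = sim$trace,
         area_trace = atrace, calibration = calib, volume_trace = vtrace,
         metrics = metrics, comparison = comparison),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (config hash ", substr(x$config_hash, 1, 8), ")\n",
      sep = "")
  cat(sprintf("  true SV %.4g um^3, HR %.4g Hz\n",
              x$truth$stroke_volume, x$truth$heart_rate_hz))
  for (m in names(x$metrics))
    cat(sprintf("  %-12s SV %.4g um^3, HR %.4g Hz, EF %.3g\n", m,
                x$metrics[[m]]$stroke_volume, x$metrics[[m]]$heart_rate_hz,
                x$metrics[[m]]$ejection_fraction))
  invisible(x)
}
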