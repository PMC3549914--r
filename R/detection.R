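#' Detection parameters for ventricle segmentation
#'
#' Mirrors the threshold / gap-fill / size-exclusion detection used for the
#' fluorescent ventricle: keep pixels inside an intensity band, label
#' 4-connected components, optionally fill interior holes, and discard
#' objects smaller than `min_area` (1000 um^2 by default, which removes
#' debris and the atrium at typical magnifications).
#'
#' @param intensity_range c(lo, hi) inclusive intensity band, in the image's
#'   native units (no rescaling is applied).
#' @param fill_gaps fill interior holes before measuring area (default TRUE).
#' @param min_area minimum object area to keep (um^2, default 1000).
#' @param selection_rule when several objects survive in a frame: `"largest"`
#'   (by area, default) or `"brightest"` (by mean intensity).
#' @param max_missing_fraction maximum tolerated fraction of frames with no
#'   surviving object (default 0.10); beyond it [detect_area_trace] errors.
#' @return a validated list of class `detection_params`.
#' @export
detection_params <- function(intensity_range, fill_gaps = TRUE,
                             min_area = 1000,
                             selection_rule = c("largest", "brightest"),
                             max_missing_fraction = 0.10) {
  stopifnot(length(intensity_range) == 2)
  if (intensity_range[1] >= intensity_range[2])
    stop("detection_params: degenerate intensity band (lo >= hi)")
  if (min_area < 0) stop("detection_params: min_area must be >= 0")
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("detection_params: max_missing_fraction must be in [0, 1]")
  structure(
    list(intensity_range = as.numeric(intensity_range),
         fill_gaps = isTRUE(fill_gaps), min_area = min_area,
         selection_rule = match.arg(selection_rule),
         max_missing_fraction = max_missing_fraction),
    class = "detection_params")
}

#' Segment one frame into candidate ventricle objects
#'
#' Pixels with intensity inside the band are labelled into 4-connected
#' components (EBImage); with `fill_gaps` the interior holes of each
#' component are filled before areas are measured. Objects below `min_area`
#' are discarded. Areas are pixel counts times `pixel_size^2`.
#'
#' @param frame numeric matrix of intensities.
#' @param params a [detection_params] object.
#' @param pixel_size um per pixel.
#' @return data frame with one row per surviving object: `area_um2`,
#'   `n_pixels`, `centroid_row`, `centroid_col`, `mean_intensity`, sorted by
#'   decreasing area. Zero rows when nothing survives.
#' @export
segment_frame <- function(frame, params, pixel_size) {
  stopifnot(is.matrix(frame), length(frame) > 0,
            inherits(params, "detection_params"), pixel_size > 0)
  lo <- params$intensity_range[1]
  hi <- params$intensity_range[2]
  mask <- frame >= lo & frame <= hi
  storage.mode(mask) <- "integer"
  if (params$fill_gaps) mask <- EBImage::imageData(EBImage::fillHull(mask))
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  n_obj <- max(labels)
  if (n_obj == 0) return(empty_objects())
  counts <- tabulate(labels[labels > 0], nbins = n_obj)
  areas <- counts * pixel_size^2
  keep <- which(areas >= params$min_area)
  if (length(keep) == 0) return(empty_objects())
  out <- do.call(rbind, lapply(keep, function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    data.frame(area_um2 = areas[l], n_pixels = counts[l],
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
               mean_intensity = mean(frame[idx]))
  }))
  out[order(-out$area_um2), , drop = FALSE]
}

empty_objects <- function() {
  data.frame(area_um2 = numeric(0), n_pixels = integer(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             mean_intensity = numeric(0))
}

#' Detect the ventricular area trace of a frame stack
#'
#' Runs [segment_frame] on every frame and keeps one object per frame by the
#' selection rule. Frames with no surviving object are flagged missing and
#' their area filled by linear interpolation from the neighbouring detected
#' frames (nearest detected value at the trace ends). If the missing
#' fraction exceeds `max_missing_fraction` the trace is rejected.
#'
#' @param stack a [frame_stack].
#' @param params a [detection_params] object.
#' @return an [area_trace]; its `missing` field marks interpolated frames.
#' @export
detect_area_trace <- function(stack, params) {
  stopifnot(inherits(stack, "frame_stack"), inherits(params, "detection_params"))
  n <- stack$n_frames
  area <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    obj <- segment_frame(stack$frames[[i]], params, stack$pixel_size)
    if (nrow(obj) > 0) {
      pick <- if (params$selection_rule == "largest")
        which.max(obj$area_um2) else which.max(obj$mean_intensity)
      area[i] <- obj$area_um2[pick]
    }
  }
  miss <- is.na(area)
  if (all(miss))
    stop("detect_area_trace: no frame contains a surviving object; check the intensity band and min_area")
  frac <- mean(miss)
  if (frac > params$max_missing_fraction)
    stop(sprintf(
      "detect_area_trace: %.1f%% of frames have no surviving object (limit %.1f%%)",
      100 * frac, 100 * params$max_missing_fraction))
  if (any(miss)) {
    ok <- which(!miss)
    area[miss] <- stats::approx(ok, area[ok], xout = which(miss),
                                rule = 2)$y
  }
  area_trace(area, sample_rate = stack$frame_rate, missing = miss)
}
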