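#' Linear area-to-C-radius calibration model
#'
#' The ventricle is modelled as a prolate spheroid, V = (4/3) pi x y z. With
#' the in-plane cross-section entering only through its area A = pi x y and
#' the optical-axis semi-axis z = C, the chamber volume is V = (4/3) A C.
#' The C radius is not observable in a single-plane movie, so it is predicted
#' from area through a linear calibration C(A) = slope * A + intercept fitted
#' on arrested hearts.
#'
#' @param slope per-um^2 change of the C radius (um^-1).
#' @param intercept C radius at zero area (um).
#' @param n_pairs number of calibration pairs behind the fit.
#' @param r_squared coefficient of determination of the fit.
#' @param valid_area_range area range (um^2) over which the model was
#'   calibrated (calibration areas +/- 20%); conversion outside it warns.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept, n_pairs = NA_integer_,
                              r_squared = NA_real_,
                              valid_area_range = NULL) {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  if (!is.na(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12))
    stop("calibration_model: r_squared outside [0, 1]")
  structure(
    list(slope = slope, intercept = intercept, n_pairs = n_pairs,
         r_squared = r_squared, valid_area_range = valid_area_range),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: C(A) = %.6g * A + %.6g um (n = %s, R^2 = %s)\n",
              x$slope, x$intercept,
              ifelse(is.na(x$n_pairs), "?", x$n_pairs),
              ifelse(is.na(x$r_squared), "?", sprintf("%.4f", x$r_squared))))
  if (!is.null(x$valid_area_range))
    cat(sprintf("  valid area range: %.5g - %.5g um^2\n",
                x$valid_area_range[1], x$valid_area_range[2]))
  invisible(x)
}

#' Fit the arrested-heart calibration
#'
#' For each (area, volume) pair the C radius is recovered by inverting the
#' prolate-spheroid relation, C_i = 3 V_i / (4 A_i), and C is regressed on A
#' by ordinary least squares (free intercept). The reference calibration on
#' five arrested 5-dpf hearts gives C = 6.8e-4 * A + 46.
#'
#' @param pairs data frame with columns `area_um2` and `volume_um3`, one row
#'   per arrested heart (both positive).
#' @return a [calibration_model] with `slope`, `intercept`, `n_pairs`,
#'   `r_squared` and the valid area range (observed areas +/- 20%).
#' @export
fit_calibration <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("area_um2", "volume_um3") %in% names(pairs)))
  a <- pairs$area_um2
  v <- pairs$volume_um3
  if (length(a) < 2) stop("fit_calibration: need at least 2 pairs")
  if (any(a <= 0) || any(v <= 0))
    stop("fit_calibration: areas and volumes must be positive")
  if (length(unique(a)) < 2)
    stop("fit_calibration: all areas equal; slope is not identifiable")
  cc <- 3 * v / (4 * a)
  fit <- stats::lm(cc ~ a)
  coefs <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((cc - mean(cc))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  calibration_model(
    slope = unname(coefs["a"]), intercept = unname(coefs["(Intercept)"]),
    n_pairs = length(a), r_squared = max(0, min(1, r2)),
    valid_area_range = c(0.8 * min(a), 1.2 * max(a)))
}

#' Convert a cross-sectional area to chamber volume
#'
#' Evaluates V = (4/3) A C(A) with C(A) = slope * A + intercept. Strictly
#' increasing in A when slope and intercept are positive.
#'
#' @param area ventricular cross-sectional area(s) in um^2 (>= 0).
#' @param model a [calibration_model].
#' @param warn_extrapolation warn when `area` falls outside the model's
#'   calibrated range (default `TRUE`).
#' @return volume(s) in um^3.
#' @export
area_to_volume <- function(area, model, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(area < 0)) stop("area_to_volume: negative area")
  cc <- model$slope * area + model$intercept
  bad <- which(area > 0 & cc <= 0)
  if (length(bad) > 0)
    stop(sprintf(
      "area_to_volume: C(A) <= 0 at area %.5g um^2; model is only valid where C(A) = %.4g*A + %.4g > 0",
      area[bad[1]], model$slope, model$intercept))
  if (warn_extrapolation && !is.null(model$valid_area_range)) {
    rng <- model$valid_area_range
    out <- area > 0 & (area < rng[1] | area > rng[2])
    if (any(out))
      warning(sprintf(
        "area_to_volume: %d area value(s) outside the calibrated range [%.5g, %.5g] um^2",
        sum(out), rng[1], rng[2]))
  }
  (4 / 3) * area * cc
}

#' Invert the prolate-spheroid mapping: volume to area
#'
#' Solves (4/3) A (slope * A + intercept) = V for the non-negative root A.
#' This is the exact algebraic inverse of [area_to_volume] and is used by the
#' simulator to decide what area to render for a target volume.
#'
#' @param volume volume(s) in um^3 (>= 0).
#' @param model a [calibration_model].
#' @return area(s) in um^2.
#' @export
volume_to_area <- function(volume, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(volume < 0)) stop("volume_to_area: negative volume")
  s <- model$slope
  i <- model$intercept
  if (abs(s) < .Machine$double.eps) {
    if (i <= 0) stop("volume_to_area: non-positive constant C radius")
    return(3 * volume / (4 * i))
  }
  # (4s/3) A^2 + (4i/3) A - V = 0, take the root that is >= 0
  disc <- i^2 + 3 * s * volume
  if (any(disc < 0)) stop("volume_to_area: no real non-negative root")
  (-i + sqrt(disc)) / (2 * s)
}

#' Convert an area trace to a volume trace
#'
#' Applies [area_to_volume] frame by frame; the time grid and missing-frame
#' mask are preserved.
#'
#' @param trace an [area_trace].
#' @param model a [calibration_model].
#' @param warn_extrapolation passed to [area_to_volume].
#' @return a [volume_trace].
#' @export
convert_trace <- function(trace, model, warn_extrapolation = TRUE) {
  stopifnot(inherits(trace, "area_trace"))
  vol <- tryCatch(
    area_to_volume(trace$area, model, warn_extrapolation = warn_extrapolation),
    error = function(e) {
      cc <- model$slope * trace$area + model$intercept
      idx <- which(trace$area < 0 | cc <= 0)
      stop(sprintf("convert_trace: frame %d: %s",
                   if (length(idx)) idx[1] else NA_integer_,
                   conditionMessage(e)), call. = FALSE)
    })
  volume_trace(vol, sample_rate = trace$sample_rate,
               missing = trace$missing, time = trace$time)
}
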