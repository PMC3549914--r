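#' Plan a well-plate confocal acquisition
#'
#' An acquisition takes `n_stacks` z-stacks at distinct x-y locations per
#' well and `n_slices` slices per stack at `z_spacing` um steps. Total
#' images per well and the z-range spanned between first and last slice
#' centres follow arithmetically: the reference geometry of 9 stacks x 6
#' slices at 50 um gives 54 images over 250 um.
#'
#' @param n_stacks z-stacks (x-y locations) per well (>= 1).
#' @param n_slices z-slices per stack (>= 1).
#' @param z_spacing spacing between slices (um, > 0).
#' @return an object of class `well_plan` with `total_images` and `z_range`.
#' @export
plan_acquisition <- function(n_stacks, n_slices, z_spacing) {
  if (n_stacks < 1 || n_slices < 1 || z_spacing <= 0)
    stop("plan_acquisition: counts must be >= 1 and z_spacing > 0")
  structure(
    list(n_stacks = as.integer(n_stacks), n_slices = as.integer(n_slices),
         z_spacing = z_spacing,
         total_images = as.integer(n_stacks) * as.integer(n_slices),
         z_range = (as.integer(n_slices) - 1) * z_spacing),
    class = "well_plan")
}

#' @export
print.well_plan <- function(x, ...) {
  cat(sprintf(
    "well_plan: %d stacks x %d slices @ %.4g um -> %d images/well, z-range %.4g um\n",
    x$n_stacks, x$n_slices, x$z_spacing, x$total_images, x$z_range))
  invisible(x)
}

#' Quantify the fluorescence of one well
#'
#' The well's readout is the mean fluorescence intensity over all pixels of
#' all its images; the SEM is computed over the per-image means (one mean
#' per image, divided by sqrt of the image count), matching per-stack error
#' bars rather than per-pixel ones.
#'
#' @param images list of numeric image matrices for one well.
#' @param plan a [well_plan]; the image count must match
#'   `plan$total_images` unless `allow_count_mismatch`.
#' @param well_id identifier carried into the result.
#' @param allow_count_mismatch accept an image count different from the plan.
#' @return data frame row with `well_id`, `mean_intensity`, `sem`, `n_images`.
#' @export
quantify_well <- function(images, plan, well_id = "well",
                          allow_count_mismatch = FALSE) {
  stopifnot(is.list(images), length(images) >= 1, inherits(plan, "well_plan"))
  if (length(images) != plan$total_images && !allow_count_mismatch)
    stop(sprintf(
      "quantify_well: %d image(s) but the plan expects %d; pass allow_count_mismatch = TRUE to override",
      length(images), plan$total_images))
  per_image <- vapply(images, mean, numeric(1))
  n <- length(per_image)
  sem <- if (n > 1) stats::sd(per_image) / sqrt(n) else 0
  data.frame(well_id = well_id,
             mean_intensity = mean(unlist(images)),
             sem = sem, n_images = n, stringsAsFactors = FALSE)
}

#' Summarise well results by treatment group
#'
#' Computes per-group mean, SEM and n of the per-well mean intensities.
#' Wells reading exactly zero (no signal) are excluded by default; a group
#' emptied by the exclusion is kept in the output with `n = 0` and flagged,
#' with a warning, rather than silently dropped.
#'
#' @param well_results data frame with columns `well_id`, `treatment`,
#'   `mean_intensity` (e.g. rows from [quantify_well] plus a treatment map).
#' @param exclude_zero drop wells with `mean_intensity == 0` (default TRUE).
#' @return data frame with `treatment`, `mean`, `sem`, `n`, `excluded_all`.
#' @export
summarize_groups <- function(well_results, exclude_zero = TRUE) {
  stopifnot(is.data.frame(well_results),
            all(c("treatment", "mean_intensity") %in% names(well_results)))
  groups <- unique(well_results$treatment)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- well_results$mean_intensity[well_results$treatment == g]
    if (exclude_zero) x <- x[x != 0]
    n <- length(x)
    data.frame(treatment = g,
               mean = if (n > 0) mean(x) else NA_real_,
               sem = if (n > 1) stats::sd(x) / sqrt(n) else
                 if (n == 1) 0 else NA_real_,
               n = n, excluded_all = n == 0, stringsAsFactors = FALSE)
  }))
  if (any(out$excluded_all))
    warning("summarize_groups: group(s) emptied by zero-exclusion: ",
            paste(out$treatment[out$excluded_all], collapse = ", "))
  out
}

#' Linear dose-response fit
#'
#' Ordinary least-squares fit of response on dose, reporting slope,
#' intercept and R^2. At least three distinct doses are required for the
#' fit to say anything about a trend.
#'
#' @param doses numeric dose vector.
#' @param responses numeric response vector, same length.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
dose_response_fit <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  if (length(unique(doses)) < 3)
    stop("dose_response_fit: need at least 3 distinct doses")
  if (stats::var(doses) == 0)
    stop("dose_response_fit: zero dose variance")
  fit <- stats::lm(responses ~ doses)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((responses - mean(responses))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (sst > 0) 1 - ssr / sst else 1,
       n = length(doses))
}
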