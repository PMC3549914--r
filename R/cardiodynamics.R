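#' One-sided amplitude spectrum of a volume trace
#'
#' The trace is mean-subtracted, multiplied by a Tukey tapered-cosine window
#' (tapered fraction `tukey_r`), and Fourier transformed. One-sided
#' magnitudes are normalised by the sum of the window samples — which
#' corrects simultaneously for trace length and the window's coherent gain —
#' and all non-DC (and non-Nyquist) bins are doubled, so a sinusoid whose
#' frequency falls on a bin reads its true amplitude. The spectral peak is
#' the argmax of amplitude inside the physiological band; frequency
#' resolution is 1/duration (0.125 Hz for an 8-s acquisition).
#'
#' @param trace a [volume_trace].
#' @param tukey_r tapered fraction of the Tukey window (default 0.5).
#' @param band c(lo, hi) physiological frequency band in Hz for the peak
#'   search (default 0.5-5 Hz, bracketing larval heart rates).
#' @return a list of class `spectral_result`: `frequencies` (Hz),
#'   `amplitudes` (um^3), `peak_frequency`, `peak_amplitude`, `tukey_r`,
#'   `band`.
#' @export
fourier_spectrum <- function(trace, tukey_r = 0.5, band = c(0.5, 5.0)) {
  stopifnot(inherits(trace, "volume_trace"), length(band) == 2,
            band[1] < band[2], band[1] > 0)
  if (trace$duration < 2 / band[1])
    stop(sprintf(
      "fourier_spectrum: trace (%.3g s) shorter than 2 periods of the lowest band frequency (%.3g Hz)",
      trace$duration, band[1]))
  n <- length(trace$volume)
  w <- tukey_window(n, tukey_r)
  x <- (trace$volume - mean(trace$volume)) * w
  spec <- stats::fft(x)
  half <- floor(n / 2) + 1
  amp <- Mod(spec[seq_len(half)]) / sum(w)
  # double the one-sided bins that have a conjugate partner
  dbl <- 2:(if (n %% 2 == 0) half - 1 else half)
  amp[dbl] <- 2 * amp[dbl]
  freqs <- (seq_len(half) - 1) * trace$sample_rate / n
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0)
    stop("fourier_spectrum: no frequency bin inside the search band")
  pk <- in_band[which.max(amp[in_band])]
  if (amp[pk] <= 1e-9 * max(mean(trace$volume), 1))
    stop("fourier_spectrum: no dominant frequency (flat spectrum in band)")
  structure(
    list(frequencies = freqs, amplitudes = amp,
         peak_frequency = freqs[pk], peak_amplitude = amp[pk],
         tukey_r = tukey_r, band = band),
    class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf(
    "spectral_result: peak %.4g um^3 at %.4g Hz (Tukey r = %.2g, band %.2g-%.2g Hz, df = %.4g Hz)\n",
    x$peak_amplitude, x$peak_frequency, x$tukey_r, x$band[1], x$band[2],
    x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Cardiac metrics by the pure frequency-domain (Fourier) method
#'
#' The normalised spectral peak amplitude is half the peak-to-peak volume
#' change, so SV = 2 x peak amplitude; HR is the peak frequency. Mean
#' diastolic and systolic volumes are placed symmetrically at the trace mean
#' +/- SV/2. Because the spectral amplitude reflects only the fundamental,
#' this method reads low on harmonic-rich (non-sinusoidal) waveforms.
#'
#' @param trace a [volume_trace].
#' @param tukey_r,band passed to [fourier_spectrum].
#' @return a [cardiac_metrics] with `method = "fourier"`.
#' @export
fourier_metrics <- function(trace, tukey_r = 0.5, band = c(0.5, 5.0)) {
  spec <- fourier_spectrum(trace, tukey_r = tukey_r, band = band)
  sv <- 2 * spec$peak_amplitude
  m <- mean(trace$volume)
  cardiac_metrics(
    stroke_volume = sv, heart_rate_hz = spec$peak_frequency,
    mean_diastolic_volume = m + sv / 2, mean_systolic_volume = m - sv / 2,
    method = "fourier")
}

#' Cardiac metrics by the combined frequency/time-domain (segmentation) method
#'
#' The heart rate is estimated from the spectral peak as in
#' [fourier_metrics]; the trace is then cut into consecutive,
#' non-overlapping segments of length `segment_factor` x the period
#' (110% by default, so every segment contains at least one full systole and
#' diastole). The global maximum and minimum of each segment are averaged
#' across segments to give the mean diastolic and systolic volumes; their
#' difference is the stroke volume. A trailing remainder at least one period
#' long is kept as a short final segment; shorter remainders are discarded.
#'
#' @param trace a [volume_trace].
#' @param segment_factor segment length as a multiple of the estimated
#'   period (default 1.1).
#' @param tukey_r,band passed to [fourier_spectrum] for the HR estimate.
#' @return a [cardiac_metrics] with `method = "segmentation"` and the number
#'   of segments used.
#' @export
segmentation_metrics <- function(trace, segment_factor = 1.1,
                                 tukey_r = 0.5, band = c(0.5, 5.0)) {
  stopifnot(segment_factor >= 1)
  spec <- fourier_spectrum(trace, tukey_r = tukey_r, band = band)
  period <- 1 / spec$peak_frequency
  seg_len <- segment_factor * period
  n_full <- floor(trace$duration / seg_len)
  remainder <- trace$duration - n_full * seg_len
  n_seg <- n_full + (remainder >= period)
  if (n_seg < 1)
    stop(sprintf(
      "segmentation_metrics: trace (%.3g s) holds no usable segment at period %.3g s",
      trace$duration, period))
  seg_id <- floor(trace$time / seg_len)
  if (remainder >= period) {
    seg_id <- pmin(seg_id, n_full)  # short trailing segment
    keep <- rep(TRUE, length(seg_id))
  } else {
    keep <- seg_id < n_full         # remainder too short: discarded
  }
  maxima <- tapply(trace$volume[keep], seg_id[keep], max)
  minima <- tapply(trace$volume[keep], seg_id[keep], min)
  mean_dia <- mean(maxima)
  mean_sys <- mean(minima)
  out <- cardiac_metrics(
    stroke_volume = mean_dia - mean_sys,
    heart_rate_hz = spec$peak_frequency,
    mean_diastolic_volume = mean_dia, mean_systolic_volume = mean_sys,
    method = "segmentation", n_segments_or_beats = as.integer(n_seg))
  out$segment_length <- seg_len  # = segment_factor x estimated period
  out
}

#' Cardiac metrics by manual-style peak and trough measurement
#'
#' Emulates how a human reads the waveform: every peak and trough with
#' topographic prominence of at least `prominence_fraction` of the trace's
#' global range is marked, SV is mean(peaks) - mean(troughs), and HR is the
#' number of beat intervals divided by the time between first and last peak.
#' Serves as the reference the automated methods are validated against.
#'
#' @param trace a [volume_trace].
#' @param prominence_fraction minimum peak prominence as a fraction of the
#'   global max - min (default 0.5; robust to modest noise and harmonics).
#' @return a [cardiac_metrics] with `method = "manual"` and the peak count.
#' @export
manual_oracle_metrics <- function(trace, prominence_fraction = 0.5) {
  stopifnot(inherits(trace, "volume_trace"),
            prominence_fraction > 0, prominence_fraction <= 1)
  v <- trace$volume
  rng <- max(v) - min(v)
  if (rng <= 0) stop("manual_oracle_metrics: flat trace has no beats")
  min_prom <- prominence_fraction * rng
  peaks <- find_prominent_peaks(v, min_prom)
  troughs <- find_prominent_peaks(-v, min_prom)
  if (length(peaks) < 2)
    stop(sprintf("manual_oracle_metrics: found %d peak(s); need at least 2",
                 length(peaks)))
  if (length(troughs) < 1)
    stop("manual_oracle_metrics: no troughs found")
  mean_dia <- mean(v[peaks])
  mean_sys <- mean(v[troughs])
  hr <- (length(peaks) - 1) /
    (trace$time[peaks[length(peaks)]] - trace$time[peaks[1]])
  cardiac_metrics(
    stroke_volume = mean_dia - mean_sys, heart_rate_hz = hr,
    mean_diastolic_volume = mean_dia, mean_systolic_volume = mean_sys,
    method = "manual", n_segments_or_beats = length(peaks))
}

#' Compare the Fourier, segmentation and manual methods across traces
#'
#' Analyses every trace with all three methods and tabulates the metrics,
#' the per-trace pairwise differences, and ordinary least-squares
#' regressions of each method's cardiac output on each other method's
#' (slope and R^2), the standard way to check that two analysis paradigms
#' detect the same physiology.
#'
#' @param traces list of [volume_trace] objects (optionally named).
#' @param segment_factor,tukey_r,band,prominence_fraction analysis settings
#'   passed through to the individual methods.
#' @return a list of class `method_comparison`: `metrics` (long data frame,
#'   one row per trace x method), `differences` (per-trace pairwise metric
#'   differences), `regressions` (CO-vs-CO slope and R^2 per method pair)
#'   and `failures` (traces a method could not analyse, with the message;
#'   never silently dropped).
#' @export
compare_methods <- function(traces, segment_factor = 1.1, tukey_r = 0.5,
                            band = c(0.5, 5.0), prominence_fraction = 0.5) {
  stopifnot(is.list(traces), length(traces) >= 1)
  ids <- names(traces)
  if (is.null(ids)) ids <- sprintf("trace%03d", seq_along(traces))
  runners <- list(
    fourier = function(tr) fourier_metrics(tr, tukey_r, band),
    segmentation = function(tr)
      segmentation_metrics(tr, segment_factor, tukey_r, band),
    manual = function(tr) manual_oracle_metrics(tr, prominence_fraction))
  rows <- list()
  fails <- list()
  for (i in seq_along(traces)) {
    for (m in names(runners)) {
      res <- tryCatch(runners[[m]](traces[[i]]), error = identity)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1]] <- data.frame(
          trace_id = ids[i], method = m, message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <-
          cbind(data.frame(trace_id = ids[i]), as.data.frame(res))
      }
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(trace_id = character(0), method = character(0),
               message = character(0))
  diffs <- regs <- NULL
  if (!is.null(metrics)) {
    pairs <- utils::combn(names(runners), 2, simplify = FALSE)
    dl <- list()
    rl <- list()
    for (p in pairs) {
      a <- metrics[metrics$method == p[1], ]
      b <- metrics[metrics$method == p[2], ]
      common <- intersect(a$trace_id, b$trace_id)
      if (length(common) == 0) next
      a <- a[match(common, a$trace_id), ]
      b <- b[match(common, b$trace_id), ]
      for (mcol in c("sv_um3", "hr_hz", "co_um3_s", "ef")) {
        dl[[length(dl) + 1]] <- data.frame(
          trace_id = common, method_a = p[1], method_b = p[2],
          metric = mcol, difference = a[[mcol]] - b[[mcol]])
      }
      if (length(common) >= 3 && stats::var(b$co_um3_s) > 0) {
        fit <- stats::lm(a$co_um3_s ~ b$co_um3_s)
        rl[[length(rl) + 1]] <- data.frame(
          method_a = p[1], method_b = p[2],
          slope = unname(stats::coef(fit)[2]),
          intercept = unname(stats::coef(fit)[1]),
          r_squared = summary(fit)$r.squared,
          n = length(common))
      }
    }
    diffs <- if (length(dl)) do.call(rbind, dl) else NULL
    regs <- if (length(rl)) do.call(rbind, rl) else NULL
  }
  structure(list(metrics = metrics, differences = diffs,
                 regressions = regs, failures = failures),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  n_tr <- if (is.null(x$metrics)) 0 else length(unique(x$metrics$trace_id))
  cat(sprintf("method_comparison: %d trace(s), %d failure(s)\n",
              n_tr, nrow(x$failures)))
  if (!is.null(x$regressions)) {
    cat("CO-vs-CO regressions:\n")
    print(x$regressions, row.names = FALSE)
  }
  invisible(x)
}
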