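#' Tukey (tapered cosine) window
#'
#' `r` is the fraction of the window that is tapered: `r = 0` gives a
#' rectangular window, `r = 1` a Hann window. Spectral amplitudes normalized
#' by `sum(tukey_window(n, r))` read a sinusoid's true amplitude (coherent
#' gain correction).
#'
#' @param n window length in samples.
#' @param r tapered fraction, in \[0, 1\].
#' @return numeric vector of length `n`.
#' @export
tukey_window <- function(n, r = 0.5) {
  stopifnot(n >= 1, r >= 0, r <= 1)
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (r > 0) {
    lo <- x < r / 2
    hi <- x > 1 - r / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / r - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / r - 2 / r + 1)))
  }
  w
}

# Strict local maxima of a numeric vector (interior points only).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] > x[i + 1]]
}

# Topographic prominence of each peak: height above the higher of the two key
# saddles (the minimum between the peak and the nearest higher terrain on each
# side; trace ends count as walls).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- if (p > 1) x[seq_len(p - 1)] else numeric(0)
    right <- if (p < length(x)) x[seq(p + 1, length(x))] else numeric(0)
    key <- function(side, rev = FALSE) {
      if (length(side) == 0) return(min(x))
      if (rev) side <- rev(side)
      higher <- which(side > x[p])
      if (length(higher) > 0) side <- side[seq_len(higher[1] - 1)]
      if (length(side) == 0) return(x[p])
      min(side)
    }
    x[p] - max(key(left, rev = TRUE), key(right))
  }, numeric(1))
}

# Peaks whose prominence is at least `min_prominence`.
find_prominent_peaks <- function(x, min_prominence) {
  pk <- local_maxima(x)
  if (length(pk) == 0) return(integer(0))
  pk[peak_prominence(x, pk) >= min_prominence]
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
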