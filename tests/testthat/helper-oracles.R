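# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: labeling is a plain BFS flood fill, cycle extrema
# are taken straight from the sampled vector.

# Exhaustive 4-connected component labeling of a logical mask (for small
# frames). Returns an integer matrix of labels, 0 = background.
flood_fill_label <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      r <- ((p - 1) %% nr) + 1
      c <- ((p - 1) %/% nr) + 1
      for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (d[1] < 1 || d[1] > nr || d[2] < 1 || d[2] > nc) next
        q <- (d[2] - 1) * nr + d[1]
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- current
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Brute-force per-cycle extrema: cut the sampled trace into consecutive
# whole periods of length `period` starting at t = 0 and average the sampled
# max and min of each complete cycle.
per_cycle_extrema_sv <- function(trace, period) {
  cycle <- floor(trace$time / period)
  complete <- cycle < floor(trace$duration / period)
  cyc <- cycle[complete]
  v <- trace$volume[complete]
  maxima <- tapply(v, cyc, max)
  minima <- tapply(v, cyc, min)
  list(sv = mean(maxima) - mean(minima),
       mean_diastolic = mean(maxima), mean_systolic = mean(minima),
       n_cycles = length(maxima))
}

# Draw a frame with rectangular blobs of given side lengths (px), spaced so
# they never touch; returns the frame and the per-blob pixel counts.
frame_with_blobs <- function(sides, shape = c(120, 220), fg = 0.8, bg = 0.1) {
  f <- matrix(bg, shape[1], shape[2])
  col0 <- 5
  for (s in sides) {
    f[10:(10 + s - 1), col0:(col0 + s - 1)] <- fg
    col0 <- col0 + s + 5
  }
  f
}

default_model <- function() calibration_model(6.8e-4, 46)
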