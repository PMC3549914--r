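sinusoid_trace <- function(baseline = 500, amp = 100, hr = 2.5,
                           fs = 22.75, dur = 8) {
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs
  volume_trace(baseline + amp * sin(2 * pi * hr * t), sample_rate = fs)
}

test_that("Tukey window hits its rectangular and Hann limits", {
  expect_equal(tukey_window(64, 0), rep(1, 64))
  n <- 65
  hann <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  expect_equal(tukey_window(n, 1), hann, tolerance = 1e-12)
  w <- tukey_window(100, 0.5)
  expect_equal(w, rev(w), tolerance = 1e-12)   # symmetry
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w[26:75], rep(1, 50))           # flat middle for r = 0.5
})

test_that("an in-bin sinusoid reads its true amplitude and frequency", {
  tr <- sinusoid_trace()  # 2.5 Hz is bin 20 of a 0.125 Hz grid
  sp <- fourier_spectrum(tr)
  expect_equal(sp$peak_frequency, 2.5, tolerance = 1e-12)
  expect_equal(sp$peak_amplitude, 100, tolerance = 0.01 * 100)
  expect_equal(sp$frequencies[2] - sp$frequencies[1], 0.125)
  # amplitude ordering: a weaker second tone does not shift the peak
  t <- tr$time
  two <- volume_trace(500 + 100 * sin(2 * pi * 2.5 * t) +
                        30 * sin(2 * pi * 5 * t), sample_rate = 22.75)
  expect_equal(fourier_spectrum(two)$peak_frequency, 2.5)
})

test_that("degenerate spectra are rejected rather than silently zero", {
  flat <- volume_trace(rep(500, 182), sample_rate = 22.75)
  expect_error(fourier_spectrum(flat), "no dominant frequency")
  expect_error(fourier_metrics(flat), "no dominant frequency")
  # near-flat trace: tiny noise must not masquerade as a heartbeat
  wiggle <- withr::with_seed(2, volume_trace(500 + stats::rnorm(182, 0, 1e-7),
                                             sample_rate = 22.75))
  expect_error(segmentation_metrics(wiggle), "no dominant frequency")
  short <- sinusoid_trace(dur = 2)
  expect_error(fourier_spectrum(short), "shorter than 2 periods")
})

test_that("Fourier metrics follow the doubled-peak construction", {
  tr <- sinusoid_trace()
  fm <- fourier_metrics(tr)
  sp <- fourier_spectrum(tr)
  expect_identical(fm$stroke_volume, 2 * sp$peak_amplitude)
  expect_equal(fm$stroke_volume, 200, tolerance = 2)
  expect_equal(fm$heart_rate_hz, 2.5)
  expect_equal(fm$cardiac_output, 500, tolerance = 5)
  expect_equal(fm$ejection_fraction, 200 / 600, tolerance = 0.005)
  expect_equal(fm$mean_diastolic_volume + fm$mean_systolic_volume,
               2 * mean(tr$volume), tolerance = 1e-9)
})

test_that("segmentation equals the brute-force per-cycle extrema oracle", {
  for (hr in c(2.0, 2.5, 3.0)) {
    tr <- sinusoid_trace(hr = hr)
    sm <- segmentation_metrics(tr)
    expect_equal(sm$segment_length * sm$heart_rate_hz, 1.1, tolerance = 1e-12)
    oracle <- per_cycle_extrema_sv(tr, 1.1 / sm$heart_rate_hz)
    expect_equal(sm$stroke_volume, oracle$sv, tolerance = 1e-9)
    expect_equal(sm$mean_diastolic_volume, oracle$mean_diastolic,
                 tolerance = 1e-9)
    expect_equal(sm$n_segments_or_beats, oracle$n_cycles)
  }
})

test_that("segmentation keeps a trailing remainder only when it spans a period", {
  tr <- sinusoid_trace()  # T = 0.4 s, seg 0.44 s: 18 full, remainder 0.08 s
  sm <- segmentation_metrics(tr)
  expect_equal(sm$n_segments_or_beats, 18L)
  # 6-s trace: 13 full segments (5.72 s), remainder 0.28 s < T -> discarded
  sm6 <- segmentation_metrics(sinusoid_trace(dur = 6))
  expect_equal(sm6$n_segments_or_beats, 13L)
})

test_that("manual peak-trough measurement matches segmentation on clean data", {
  tr <- sinusoid_trace()
  mm <- manual_oracle_metrics(tr)
  sm <- segmentation_metrics(tr)
  expect_equal(mm$stroke_volume, sm$stroke_volume,
               tolerance = 0.01 * sm$stroke_volume)
  expect_equal(mm$heart_rate_hz, 2.5, tolerance = 0.05)
  # fewer than two peaks is an error, not a zero
  half <- volume_trace(500 + 100 * sin(2 * pi * 0.5 *
                                         (0:45) / 22.75)[1:23],
                       sample_rate = 22.75)
  expect_error(manual_oracle_metrics(half), "need at least 2")
  expect_error(manual_oracle_metrics(volume_trace(rep(5, 50), 10)), "flat")
})

test_that("harmonic-rich waveforms make the Fourier method read low", {
  withr::with_seed(55, {
    n_ok <- 0
    for (i in 1:100) {
      h <- c(stats::runif(1, 0.2, 0.5), stats::runif(1, 0, 0.25))
      sim <- generate_volume_trace(waveform_params(harmonic_amplitudes = h,
                                                   seed = 5000 + i))
      f <- fourier_metrics(sim$trace)
      g <- segmentation_metrics(sim$trace)
      if (f$stroke_volume <= g$stroke_volume) n_ok <- n_ok + 1
      # the fundamental alone underestimates the true peak-to-peak
      expect_lt(f$stroke_volume, sim$truth$stroke_volume)
    }
    expect_equal(n_ok, 100)
  })
})

test_that("segmentation tracks manual measurement closer than Fourier on erratic beats", {
  for (s in 1:12) {
    sim <- generate_volume_trace(waveform_params(
      erratic_jitter = 0.3, harmonic_amplitudes = c(0.3, 0.15), seed = s))
    tr <- sim$trace
    f <- fourier_metrics(tr)
    g <- segmentation_metrics(tr)
    m <- manual_oracle_metrics(tr, prominence_fraction = 0.25)
    expect_lte(abs(g$stroke_volume - m$stroke_volume),
               abs(f$stroke_volume - m$stroke_volume))
  }
})

test_that("heart rate is recovered within one frequency bin across the band", {
  withr::with_seed(66, {
    for (i in 1:25) {
      hr <- stats::runif(1, 1.5, 4.5)
      sim <- generate_volume_trace(waveform_params(heart_rate = hr,
                                                   seed = 600 + i))
      fm <- fourier_metrics(sim$trace)
      expect_lt(abs(fm$heart_rate_hz - hr), 1 / sim$trace$duration + 1e-12)
    }
  })
})

test_that("segmentation recovers stroke volume within 5% under 5% noise", {
  errs <- vapply(1:50, function(s) {
    sim <- generate_volume_trace(waveform_params(noise_sd = 0.05 * 2e5,
                                                 seed = s))
    g <- segmentation_metrics(sim$trace)
    abs(g$stroke_volume - sim$truth$stroke_volume) / sim$truth$stroke_volume
  }, numeric(1))
  expect_lte(stats::median(errs), 0.05)
})

test_that("metric identities hold exactly on every method's output", {
  sim <- generate_volume_trace(waveform_params(noise_sd = 5e3,
                                               harmonic_amplitudes = 0.3,
                                               seed = 77))
  for (m in list(fourier_metrics(sim$trace),
                 segmentation_metrics(sim$trace),
                 manual_oracle_metrics(sim$trace, 0.3))) {
    expect_identical(m$cardiac_output, m$stroke_volume * m$heart_rate_hz)
    expect_identical(m$ejection_fraction,
                     m$stroke_volume / m$mean_diastolic_volume)
    expect_equal(m$stroke_volume,
                 m$mean_diastolic_volume - m$mean_systolic_volume,
                 tolerance = 1e-9)
    expect_identical(m$heart_rate_bpm, m$heart_rate_hz * 60)
    expect_identical(m$cardiac_output_nl_min, m$cardiac_output * 60 / 1e6)
  }
})

test_that("method comparison is self-consistent across a synthetic cohort", {
  svs_true <- seq(1e5, 3e5, length.out = 20)  # well-separated by construction
  traces <- withr::with_seed(88, lapply(1:20, function(i) {
    hr <- sample(seq(2.25, 2.75, by = 0.125), 1)  # on-bin rates
    generate_volume_trace(waveform_params(stroke_volume = svs_true[i],
                                          heart_rate = hr,
                                          seed = 800 + i))$trace
  }))
  cmp <- compare_methods(traces)
  expect_equal(nrow(cmp$failures), 0)
  reg <- cmp$regressions
  sm <- reg[reg$method_a == "segmentation" & reg$method_b == "manual", ]
  expect_gt(sm$slope, 0.9)
  expect_lt(sm$slope, 1.1)
  expect_gt(sm$r_squared, 0.95)
  # all methods rank the cohort identically by SV
  mx <- cmp$metrics
  svs <- split(mx$sv_um3[order(mx$trace_id)], mx$method[order(mx$trace_id)])
  expect_equal(stats::cor(svs$fourier, svs$segmentation, method = "spearman"), 1)
  expect_equal(stats::cor(svs$segmentation, svs$manual, method = "spearman"), 1)
})

test_that("identical traces give identical metrics and failures are reported", {
  tr <- sinusoid_trace()
  cmp <- compare_methods(list(a = tr, b = tr))
  d <- cmp$differences
  expect_identical(d$difference[d$trace_id == "a"],
                   d$difference[d$trace_id == "b"])
  wide <- cmp$metrics
  expect_equal(wide[wide$trace_id == "a", -1], wide[wide$trace_id == "b", -1],
               ignore_attr = TRUE)
  # a flat trace fails every method and is listed, not dropped
  flat <- volume_trace(rep(500, 182), sample_rate = 22.75)
  cmp2 <- compare_methods(list(good = tr, bad = flat))
  expect_equal(sort(unique(cmp2$failures$trace_id)), "bad")
  expect_equal(nrow(cmp2$failures), 3)
})
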