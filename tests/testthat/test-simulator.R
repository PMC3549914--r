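test_that("noiseless sinusoid trace has the closed-form sample count and bounds", {
  p <- waveform_params(baseline_volume = 500, stroke_volume = 200,
                       heart_rate = 2.5, duration = 8, sample_rate = 22.75)
  sim <- generate_volume_trace(p)
  expect_length(sim$trace$volume, 182)
  # exact sinusoid on the grid
  expect_equal(sim$trace$volume,
               500 + 100 * sin(2 * pi * 2.5 * sim$trace$time),
               tolerance = 1e-12)
  # sampled extrema within the discretization bound of baseline -/+ SV/2
  disc <- 100 * (1 - cos(pi * 2.5 / 22.75))
  expect_lte(max(sim$trace$volume), 600)
  expect_gte(max(sim$trace$volume), 600 - disc)
  expect_gte(min(sim$trace$volume), 400)
  expect_lte(min(sim$trace$volume), 400 + disc)
  # ground truth reflects the constructed waveform exactly
  expect_equal(sim$truth$stroke_volume, 200, tolerance = 1e-4)
  expect_equal(sim$truth$heart_rate_hz, 2.5, tolerance = 1e-12)
  expect_equal(sim$truth$cardiac_output, 200 * 2.5, tolerance = 1e-3)
  expect_equal(sim$truth$ejection_fraction, 200 / 600, tolerance = 1e-4)
})

test_that("generators are bitwise-deterministic under a fixed seed", {
  p <- waveform_params(baseline_volume = 500, stroke_volume = 200,
                       noise_sd = 10, erratic_jitter = 0.2, seed = 7)
  expect_identical(generate_volume_trace(p)$trace$volume,
                   generate_volume_trace(p)$trace$volume)
  m <- default_model()
  expect_identical(generate_calibration_set(10, c(5e3, 1.5e4), m, 2, seed = 3),
                   generate_calibration_set(10, c(5e3, 1.5e4), m, 2, seed = 3))
  expect_identical(generate_wellplate_set(4, 6, 100, 10, seed = 5),
                   generate_wellplate_set(4, 6, 100, 10, seed = 5))
})

test_that("erratic jitter perturbs per-beat periods around the mean heart rate", {
  # a single 8-s run holds ~20 beats, so judge the mean period over 10 runs
  all_periods <- unlist(lapply(1:10, function(s) {
    p <- waveform_params(erratic_jitter = 0.3, seed = 10 + s)
    sim <- generate_volume_trace(p)
    expect_gte(sum(sim$beats$period), p$duration)  # schedule covers the run
    sim$beats$period
  }))
  expect_gt(stats::sd(all_periods), 0)
  expect_lt(abs(mean(all_periods) - 0.4), 0.1 * 0.4)
})

test_that("invalid waveform parameters are rejected with explicit messages", {
  expect_error(waveform_params(heart_rate = 12, sample_rate = 22.75), "Nyquist")
  expect_error(waveform_params(baseline_volume = 90, stroke_volume = 200),
               "positive")
  expect_error(waveform_params(noise_sd = -1))
})

test_that("calibration pairs lie exactly on the generating line when noiseless", {
  m <- default_model()
  pairs <- generate_calibration_set(5, c(5e3, 1.5e4), m, noise_sd_C = 0)
  cc <- 3 * pairs$volume_um3 / (4 * pairs$area_um2)
  expect_equal(cc, m$slope * pairs$area_um2 + m$intercept, tolerance = 1e-12)
  expect_error(generate_calibration_set(1, c(5e3, 1.5e4), m), "n >= 2")
  # two noiseless points define the exact line
  two <- generate_calibration_set(2, c(6e3, 1.2e4), m, noise_sd_C = 0)
  fit <- fit_calibration(two)
  expect_equal(fit$slope, m$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, m$intercept, tolerance = 1e-10)
})

test_that("noisy calibration recovery stays within OLS sampling bounds", {
  m <- default_model()
  pairs <- generate_calibration_set(100, c(5e3, 1.5e4), m, noise_sd_C = 2,
                                    seed = 17)
  fit <- fit_calibration(pairs)
  # independent OLS oracle: refit with lm on the inverted C values
  cc <- 3 * pairs$volume_um3 / (4 * pairs$area_um2)
  ref <- summary(stats::lm(cc ~ pairs$area_um2))
  se_slope <- ref$coefficients[2, 2]
  se_int <- ref$coefficients[1, 2]
  expect_lt(abs(fit$slope - m$slope), 3 * se_slope)
  expect_lt(abs(fit$intercept - m$intercept), 3 * se_int)
})

test_that("rendered stacks carry the inverse prolate-spheroid area per frame", {
  m <- default_model()
  tr <- volume_trace(rep(704000, 5), sample_rate = 22.75)
  rp <- render_params(calibration = m, seed = 1)
  rr <- render_frame_stack(tr, rp)
  # root of (4/3) A (6.8e-4 A + 46) = 704000
  expect_equal(rr$true_area, rep(10000, 5), tolerance = 1e-9)
  expect_equal(rr$stack$n_frames, 5)
  # oversized ellipse errors with the first offending frame named
  small <- render_params(image_shape = c(40, 40), calibration = m, seed = 1)
  expect_error(render_frame_stack(tr, small), "frame 1")
})

test_that("well-plate image sets support the SEM scaling design", {
  # zero pixel noise -> zero SEM
  wells <- generate_wellplate_set(3, 6, c(10, 20, 30), intensity_sd = 0)
  plan <- plan_acquisition(1, 6, 50)
  res <- quantify_well(wells[[2]], plan, "W02")
  expect_equal(res$sem, 0)
  expect_equal(res$mean_intensity, 20)
  # doubling the image count shrinks the SEM by about 1/sqrt(2)
  ratio <- withr::with_seed(99, {
    sems <- replicate(150, {
      w6 <- generate_wellplate_set(1, 6, 100, 10)[[1]]
      w12 <- generate_wellplate_set(1, 12, 100, 10)[[1]]
      c(quantify_well(w6, plan_acquisition(1, 6, 50))$sem,
        quantify_well(w12, plan_acquisition(1, 12, 50))$sem)
    })
    mean(sems[2, ]) / mean(sems[1, ])
  })
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.12)
})
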