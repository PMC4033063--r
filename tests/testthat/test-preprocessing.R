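test_that("zero-lag Butterworth filtering behaves as designed", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)

  # DC gain 1
  const <- rep(3.7, length(t))
  expect_equal(zero_lag_butterworth(const, fs, "low", 10), const,
               tolerance = 1e-6)

  # strong attenuation a decade above cutoff
  s100 <- sin(2 * pi * 100 * t)
  out <- zero_lag_butterworth(s100, fs, "low", 10)
  expect_lt(sqrt(mean(out^2)), 0.01 * sqrt(mean(s100^2)))

  # passband signal comes through with zero lag
  s5 <- sin(2 * pi * 5 * t)
  out5 <- zero_lag_butterworth(s5, fs, "low", 10)
  lags <- -20:20
  xc <- vapply(lags, function(l) {
    idx <- 200:(length(t) - 200)
    cor(s5[idx], out5[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(xc)], 0)

  expect_error(zero_lag_butterworth(s5, fs, "low", 1000), "1000")
  expect_error(zero_lag_butterworth(s5, fs, "band", c(20, 2500)), "2500")

  # matrix input filters row-wise
  m <- rbind(s5, s100)
  fm <- zero_lag_butterworth(m, fs, "low", 10)
  expect_equal(fm[1, ], out5)
  expect_equal(fm[2, ], out)
})

test_that("EMG envelope is nonnegative, linear in gain, and tracks modulation", {
  fs <- 2000
  n <- 8000
  expect_equal(emg_envelope(rep(0, n), fs), rep(0, n))
  expect_error(emg_envelope(rep(0, n), 800), "1000")

  set.seed(1)
  carrier <- zero_lag_butterworth(rnorm(n), fs, "band", c(20, 500))
  carrier <- carrier / sd(carrier)
  modulation <- 0.6 + 0.4 * sin(2 * pi * 1.5 * seq_len(n) / fs)
  x <- modulation * carrier
  env <- emg_envelope(x, fs)
  expect_true(all(env >= 0))
  core <- 500:(n - 500)
  expect_gt(cor(env[core], modulation[core]), 0.9)

  # commutes with positive channel scaling
  expect_equal(emg_envelope(5 * x, fs), 5 * emg_envelope(x, fs),
               tolerance = 1e-8)
})

test_that("cycle detection recovers every impact on synthetic subjects", {
  rec <- fixture_subject()
  det <- detect_cycles(rec$accel, rec$fs)
  expect_length(det, length(rec$true_boundaries))
  expect_true(all(abs(det - rec$true_boundaries) <= 0.010 * rec$fs))

  expect_error(detect_cycles(rep(0.5, 3 * 2000), 2000),
               "insufficient step events")
  expect_error(detect_cycles(rnorm(1000), 2000), "2 s")
})

test_that("detector recall and precision are perfect across seeds", {
  hits <- vapply(1:20, function(s) {
    rec <- generate_subject(simulation_config(seed = 100 + s))
    det <- detect_cycles(rec$accel, rec$fs)
    length(det) == length(rec$true_boundaries) &&
      all(abs(det - rec$true_boundaries) <= 0.010 * rec$fs)
  }, logical(1))
  expect_true(all(hits))
})

test_that("cadence jitter does not change the boundary count", {
  for (cv in c(0, 0.05)) {
    cfg <- simulation_config(seed = 31, cycle_duration_cv = cv)
    rec <- generate_subject(cfg)
    expect_length(detect_cycles(rec$accel, rec$fs), 41)
  }
})

test_that("time normalization is linear, exact on ramps, and idempotent", {
  seg <- matrix(seq(0, 1, length.out = 2347), nrow = 1)
  out <- time_normalize(seg)
  expect_identical(ncol(out), 200L)
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 200], 1)
  expect_lt(max(abs(out[1, ] - seq(0, 1, length.out = 200))), 1e-9)

  const <- matrix(2.5, 3, 57)
  expect_equal(time_normalize(const), matrix(2.5, 3, 200))

  x <- matrix(runif(2 * 200), 2, 200)
  expect_equal(time_normalize(x), x, tolerance = 1e-12)

  expect_error(time_normalize(matrix(1, 2, 1)), "2 samples")
})

test_that("peak normalization scales rows to unit maximum", {
  m <- rbind(a = c(0, 2, 4), b = c(1, 1, 1))
  out <- peak_normalize(m)
  expect_equal(unname(apply(out, 1, max)), c(1, 1))
  expect_equal(peak_normalize(7 * m), out)
  expect_warning(z <- peak_normalize(rbind(a = c(0, 0), b = c(1, 2))),
                 "all-zero")
  expect_equal(unname(z["a", ]), c(0, 0))
  expect_error(peak_normalize(rbind(c(-1, 2))), "nonnegative")
})

test_that("preprocessing a default subject yields 40 x 10 x 200 cycles", {
  set <- fixture_set()
  expect_identical(dim(set$cycles), c(40L, 10L, 200L))
  expect_true(all(set$cycles >= 0))
  expect_identical(set$muscle_names, gait_muscles())
  expect_error(preprocess_recording(fixture_subject(), n_cycles = 80),
               "only 40 cycles available")
})

test_that("noiseless cycles round-trip through preprocessing", {
  gt <- default_ground_truth()
  cfg <- simulation_config(seed = 13, n_cycles = 8, cycle_duration_cv = 0,
                           gain_cv = 0, timing_jitter_sd = 0,
                           envelope_noise_sd = 0)
  env <- generate_cycle_envelopes(gt, cfg)
  rec <- synthesize_raw(env$envelopes, env$durations, cfg)
  set_det <- preprocess_recording(rec, n_cycles = 8)
  set_true <- preprocess_recording(rec, n_cycles = 8, use_true_boundaries = TRUE)
  truth <- gt$weightings %*% gt$activation_templates
  for (ci in 1:8) for (mi in 1:10) {
    expect_gt(cor(set_det$cycles[ci, mi, ], truth[mi, ]), 0.95)
    # detected and true segmentations agree closely
    expect_gt(cor(set_det$cycles[ci, mi, ], set_true$cycles[ci, mi, ]), 0.99)
  }
  expect_true(all(abs(set_det$boundaries - set_true$boundaries) <= 0.010 * rec$fs))
})
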