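test_that("default ground truth has the expected module structure", {
  gt <- default_ground_truth()
  W <- gt$weightings
  expect_identical(rownames(W), gait_muscles())
  expect_equal(unname(apply(W, 2, max)), rep(1, 5))
  expect_true(all(W >= 0))
  expect_equal(unname(apply(gt$activation_templates, 1, max)), rep(1, 5))

  # propulsion module recruits the plantarflexors above all other muscles
  m2_top <- names(sort(W[, "M2"], decreasing = TRUE))[1:3]
  expect_setequal(m2_top, c("SO", "GL", "GM"))

  # modules are mutually distinct in shape
  for (i in 1:4) for (j in (i + 1):5)
    expect_lte(module_similarity(W[, i], W[, j]), 0.75)
})

test_that("ground truth constructor validates and normalizes", {
  gt <- default_ground_truth()
  expect_error(ground_truth_model(-gt$weightings, gt$bursts), "nonnegative")
  expect_error(ground_truth_model(gt$weightings, gt$bursts[1:3]),
               "one burst table")
  # columns are renormalized even if supplied unscaled
  scaled <- ground_truth_model(gt$weightings * 3, gt$bursts)
  expect_equal(scaled$weightings, gt$weightings)
})

test_that("envelope generation is exact with variability off and seeded", {
  gt <- default_ground_truth()
  cfg <- simulation_config(seed = 5, n_cycles = 4, cycle_duration_cv = 0,
                           gain_cv = 0, timing_jitter_sd = 0,
                           envelope_noise_sd = 0)
  out <- generate_cycle_envelopes(gt, cfg)
  expected <- gt$weightings %*% gt$activation_templates
  for (ci in 1:4)
    expect_equal(unname(out$envelopes[ci, , ]), unname(expected),
                 tolerance = 1e-12)
  expect_equal(out$durations, rep(1.1, 4))

  out2 <- generate_cycle_envelopes(gt, cfg)
  expect_identical(out$envelopes, out2$envelopes)

  noisy1 <- generate_cycle_envelopes(gt, simulation_config(seed = 1, n_cycles = 2))
  noisy2 <- generate_cycle_envelopes(gt, simulation_config(seed = 1, n_cycles = 2))
  expect_identical(noisy1$envelopes, noisy2$envelopes)
  expect_error(simulation_config(n_cycles = 0), "n_cycles")
})

test_that("envelopes stay nonnegative under every variability setting", {
  gt <- default_ground_truth()
  for (pars in list(c(0.3, 0, 0), c(0, 5, 0), c(0, 0, 0.3), c(0.3, 5, 0.3))) {
    cfg <- simulation_config(seed = 3, n_cycles = 5, gain_cv = pars[1],
                             timing_jitter_sd = pars[2],
                             envelope_noise_sd = pars[3])
    out <- generate_cycle_envelopes(gt, cfg)
    expect_true(all(out$envelopes >= 0))
  }
})

test_that("variability calibration converges to the configured dispersion", {
  gt <- default_ground_truth()
  cfg <- simulation_config(seed = 9, n_cycles = 1000, gain_cv = 0.1,
                           cycle_duration_cv = 0.03)
  out <- generate_cycle_envelopes(gt, cfg)
  gain_cv <- apply(out$gains, 2, function(g) sd(g) / mean(g))
  expect_true(all(abs(gain_cv - 0.1) < 0.02))
  dur_cv <- sd(out$durations) / mean(out$durations)
  expect_lt(abs(dur_cv - 0.03) / 0.03, 0.20)
})

test_that("raw synthesis inverts to the generating envelope", {
  gt <- default_ground_truth()
  cfg <- simulation_config(seed = 21, n_cycles = 6, cycle_duration_cv = 0,
                           gain_cv = 0, timing_jitter_sd = 0,
                           envelope_noise_sd = 0)
  env <- generate_cycle_envelopes(gt, cfg)
  rec <- synthesize_raw(env$envelopes, env$durations, cfg)

  # length accounting: cycle samples match durations to +-1 sample per cycle
  n_gait <- diff(range(rec$true_boundaries))
  expect_lte(abs(n_gait - sum(env$durations) * cfg$fs), cfg$n_cycles)
  expect_identical(length(rec$accel), ncol(rec$emg))

  # round-trip: envelope of the raw EMG tracks the generating envelope
  envelope <- emg_envelope(rec$emg, rec$fs)
  ci <- 3L
  seg <- envelope[, rec$true_boundaries[ci]:(rec$true_boundaries[ci + 1] - 1)]
  norm_seg <- time_normalize(seg)
  truth <- env$envelopes[ci, , ]
  for (mi in 1:10)
    expect_gt(cor(norm_seg[mi, ], truth[mi, ]), 0.9)
})

test_that("zero envelopes synthesize to zero EMG", {
  cfg <- simulation_config(seed = 2, n_cycles = 2)
  env0 <- array(0, dim = c(2, 10, 200),
                dimnames = list(NULL, gait_muscles(), NULL))
  rec <- synthesize_raw(env0, c(1.1, 1.1), cfg)
  expect_true(all(rec$emg == 0))
  expect_error(synthesize_raw(env0, c(0.001, 1.1), cfg), "10 samples")
})

test_that("a default subject has 40 cycles plus a terminal boundary", {
  rec <- fixture_subject()
  expect_length(rec$true_boundaries, 41)
  total_gait_s <- diff(range(rec$true_boundaries)) / rec$fs
  expect_gt(total_gait_s, 40 * 1.1 * 0.9)
  expect_lt(total_gait_s, 60)

  rec2 <- generate_subject(simulation_config(seed = 43))
  expect_false(identical(rec$emg, rec2$emg))
})

test_that("recording constructor enforces its invariants", {
  expect_error(new_recording(matrix(0, 2, 5), numeric(4), 100),
               "equal sample counts")
  expect_error(new_recording(matrix(0, 2, 5), numeric(5), 100,
                             true_boundaries = c(3, 2)),
               "strictly increasing")
  expect_error(new_recording(matrix(0, 2, 5), numeric(5), 0), "fs")
})
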