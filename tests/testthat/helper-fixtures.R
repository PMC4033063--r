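# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# one default synthetic subject (seed 42) and its preprocessed cycle set
fixture_subject <- function() {
  memo("rec", function() generate_subject(simulation_config(seed = 42)))
}
fixture_set <- function() {
  memo("set", function() preprocess_recording(fixture_subject()))
}

# zero-variability envelopes straight from the generator (identical cycles)
fixture_noiseless_set <- function(n_cycles = 40) {
  memo(paste0("nset", n_cycles), function() {
    cfg <- simulation_config(seed = 7, n_cycles = n_cycles,
                             cycle_duration_cv = 0, gain_cv = 0,
                             timing_jitter_sd = 0, envelope_noise_sd = 0)
    env <- generate_cycle_envelopes(default_ground_truth(), cfg)
    as_step_cycle_set(env$envelopes)
  })
}

# low-noise envelope-level set (variability on, raw synthesis bypassed)
fixture_lownoise_set <- function(seed = 11, n_cycles = 20) {
  cfg <- simulation_config(seed = seed, n_cycles = n_cycles,
                           gain_cv = 0.05, timing_jitter_sd = 1,
                           envelope_noise_sd = 0.02)
  env <- generate_cycle_envelopes(default_ground_truth(), cfg)
  as_step_cycle_set(env$envelopes)
}

# ground-truth variants with 3, 4 or 6 modules. n <= 5 subsets the default
# model; n = 6 is a separate synthetic model with near-disjoint muscle
# groups, because each module must carry enough unique energy for the
# VAF-elbow rule to resolve it (appending a 6th module to the calibrated
# 5-module model leaves it largely absorbable by the others).
ground_truth_variant <- function(n_modules) {
  gt <- default_ground_truth()
  if (n_modules <= 5) {
    return(ground_truth_model(gt$weightings[, seq_len(n_modules), drop = FALSE],
                              gt$bursts[seq_len(n_modules)], gt$muscle_names))
  }
  W6 <- cbind(
    M1 = c(0.05, 0.05, 0.05, 0.05, 1.00, 0.95, 0.20, 0.05, 0.05, 0.10),
    M2 = c(0.05, 1.00, 0.85, 0.10, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    M3 = c(1.00, 0.05, 0.05, 0.05, 0.05, 0.05, 0.35, 0.05, 0.05, 0.05),
    M4 = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 1.00, 0.90, 0.10),
    M5 = c(0.20, 0.20, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 1.00),
    M6 = c(0.05, 0.05, 0.10, 1.00, 0.05, 0.05, 0.60, 0.05, 0.05, 0.05))
  b6 <- list(M1 = data.frame(center = 10, width = 4,   amplitude = 1),
             M2 = data.frame(center = 42, width = 4.5, amplitude = 1),
             M3 = data.frame(center = 82, width = 5,   amplitude = 1),
             M4 = data.frame(center = 96, width = 4,   amplitude = 1),
             M5 = data.frame(center = 63, width = 6,   amplitude = 1),
             M6 = data.frame(center = 27, width = 4,   amplitude = 1))
  ground_truth_model(W6, b6, gait_muscles())
}

# independent alternating-NNLS factorization oracle (Lawson-Hanson per
# column/row), used only to cross-check the multiplicative-update path
anls_nmf_objective <- function(X, n_modules, iters = 30, restarts = 3) {
  best <- Inf
  for (r in seq_len(restarts)) {
    W <- matrix(runif(nrow(X) * n_modules), nrow(X), n_modules)
    H <- NULL
    for (it in seq_len(iters)) {
      H <- apply(X, 2, function(col) pracma::lsqnonneg(W, col)$x)
      H <- matrix(H, nrow = n_modules)
      W <- t(matrix(apply(X, 1, function(row) pracma::lsqnonneg(t(H), row)$x),
                    nrow = n_modules))
    }
    best <- min(best, sum((X - W %*% H)^2))
  }
  best
}

# independent exhaustive assignment oracle: recursive search over pairings
brute_force_best_total <- function(simmat) {
  n <- nrow(simmat)
  rec <- function(i, free) {
    if (i > n) return(0)
    max(vapply(seq_along(free), function(j) {
      simmat[i, free[j]] + rec(i + 1L, free[-j])
    }, numeric(1)))
  }
  rec(1L, seq_len(n))
}
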