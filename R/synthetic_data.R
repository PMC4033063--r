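# Synthetic gait-EMG generator: envelopes composed from a ground-truth set of
# motor modules, modulated onto a band-limited noise carrier, plus a tibial
# accelerometer channel with one impact transient per step cycle.

#' Canonical muscle set
#'
#' The ten right-leg muscles used throughout: tibialis anterior (TA), soleus
#' (SO), gastrocnemius lateralis (GL) and medialis (GM), vastus lateralis (VL)
#' and medialis (VM), rectus femoris (RF), biceps femoris (BF), semitendinosus
#' (ST), gluteus maximus (GX).
#'
#' @return Character vector of length 10.
#' @export
gait_muscles <- function() {
  c("TA", "SO", "GL", "GM", "VL", "VM", "RF", "BF", "ST", "GX")
}

#' Construct a ground-truth motor module model
#'
#' A ground-truth model holds the muscle weightings and activation templates
#' the synthetic generator composes envelopes from. Activation templates are
#' sums of Gaussian bursts on the 0--100% cycle grid (200 points) with
#' circular wrap-around, so bursts near the end of the cycle spill into its
#' beginning as they do across consecutive heel strikes.
#'
#' @param weightings Nonnegative muscles x modules matrix; each column is
#'   max-normalized to 1.
#' @param bursts List with one element per module; each element is a data
#'   frame with columns `center` (% cycle), `width` (% cycle, Gaussian SD)
#'   and `amplitude`.
#' @param muscle_names Ordered muscle labels (rownames of `weightings`).
#' @return Object of class `ground_truth_model` with elements `muscle_names`,
#'   `weightings`, `bursts` and `activation_templates` (modules x 200, each
#'   row max-normalized to 1).
#' @seealso [default_ground_truth()]
#' @export
ground_truth_model <- function(weightings, bursts, muscle_names = rownames(weightings)) {
  weightings <- as.matrix(weightings)
  if (any(weightings < 0)) stop("weightings must be nonnegative")
  if (ncol(weightings) < 1L) stop("at least one module is required")
  if (length(bursts) != ncol(weightings))
    stop("one burst table is required per module")
  cmax <- apply(weightings, 2, max)
  if (any(cmax <= 0)) stop("every weighting column must have a positive entry")
  weightings <- sweep(weightings, 2, cmax, "/")
  rownames(weightings) <- muscle_names
  colnames(weightings) <- paste0("M", seq_len(ncol(weightings)))
  templates <- t(vapply(bursts, burst_template, numeric(200)))
  rownames(templates) <- colnames(weightings)
  structure(list(muscle_names = muscle_names,
                 weightings = weightings,
                 bursts = bursts,
                 activation_templates = templates),
            class = "ground_truth_model")
}

# evaluate a sum of circularly wrapped Gaussian bursts on the 200-point
# percent-of-cycle grid and max-normalize to exactly 1
burst_template <- function(burst_table, n_points = 200) {
  grid <- seq(0, 100, length.out = n_points)
  y <- numeric(n_points)
  for (i in seq_len(nrow(burst_table))) {
    d <- abs(grid - burst_table$center[i])
    d <- pmin(d, 100 - d)                     # circular distance in % cycle
    y <- y + burst_table$amplitude[i] * exp(-0.5 * (d / burst_table$width[i])^2)
  }
  y / max(y)
}

#' Default five-module ground truth for treadmill walking
#'
#' The canonical module set for level walking at a comfortable speed:
#'
#' * M1 — knee extensors (VL, VM) with GX and a small RF contribution,
#'   active at weight acceptance (~10% cycle);
#' * M2 — plantarflexors (SO, GL, GM), forward propulsion (~40%);
#' * M3 — TA and RF, a broad burst carrying the leg through swing (~65–95%);
#' * M4 — hamstrings (BF, ST) decelerating the leg just before the next
#'   heel strike, wrapping around the cycle boundary;
#' * M5 — a mixed ankle/RF/GX module with small bursts at the stance and
#'   swing transitions and no single dominant burst.
#'
#' @return A [ground_truth_model()] with 10 muscles and 5 modules. Columns of
#'   the weighting matrix are max-normalized; pairwise cosine similarity
#'   between distinct columns stays below 0.75 so the modules are
#'   identifiable.
#' @export
default_ground_truth <- function() {
  m <- gait_muscles()
  #            TA    SO    GL    GM    VL    VM    RF    BF    ST    GX
  W <- cbind(
    M1 = c(0.05, 0.05, 0.05, 0.05, 1.00, 0.95, 0.25, 0.05, 0.05, 0.35),
    M2 = c(0.05, 1.00, 0.90, 0.95, 0.05, 0.05, 0.05, 0.10, 0.05, 0.05),
    M3 = c(1.00, 0.05, 0.05, 0.05, 0.05, 0.05, 0.70, 0.10, 0.05, 0.05),
    M4 = c(0.10, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 1.00, 0.90, 0.10),
    M5 = c(0.30, 0.35, 0.25, 0.25, 0.05, 0.05, 0.30, 0.05, 0.05, 1.00))
  rownames(W) <- m
  bursts <- list(
    M1 = data.frame(center = 10, width = 4,   amplitude = 1),
    M2 = data.frame(center = 40, width = 4.5, amplitude = 1),
    M3 = data.frame(center = 82, width = 5,   amplitude = 1),
    M4 = data.frame(center = 96, width = 4,   amplitude = 1),
    M5 = data.frame(center = c(2, 63, 97), width = c(3, 7, 3),
                    amplitude = c(0.3, 1, 0.3)))
  ground_truth_model(W, bursts, m)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic recording generator. Defaults emulate
#' a 10-muscle treadmill-walking recording at natural cadence: 40 step cycles
#' of ~1.1 s sampled at 2000 Hz, with moderate step-to-step variability.
#'
#' @param n_cycles Number of step cycles to simulate (>= 1).
#' @param cycle_duration_mean Mean cycle duration in seconds.
#' @param cycle_duration_cv Coefficient of variation of cycle durations
#'   (lognormal); 0 disables duration variability.
#' @param fs Sampling rate in Hz; must exceed twice the upper carrier band
#'   edge.
#' @param gain_cv Per-cycle, per-module lognormal amplitude jitter CV.
#' @param timing_jitter_sd Per-cycle, per-burst shift of burst centers, SD in
#'   % of cycle (normal).
#' @param envelope_noise_sd Additive envelope noise SD as a fraction of each
#'   channel's noise-free peak; truncated at zero.
#' @param carrier_band Band edges in Hz of the EMG noise carrier.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_cycles = 40,
                              cycle_duration_mean = 1.1,
                              cycle_duration_cv = 0.03,
                              fs = 2000,
                              gain_cv = 0.10,
                              timing_jitter_sd = 2,
                              envelope_noise_sd = 0.05,
                              carrier_band = c(20, 500),
                              seed = 1L) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  disp <- c(cycle_duration_cv, gain_cv, timing_jitter_sd, envelope_noise_sd)
  if (any(disp < 0)) stop("dispersion parameters must be >= 0")
  if (fs <= 2 * carrier_band[2])
    stop(sprintf("fs (%g Hz) must exceed twice the upper carrier band edge (%g Hz)",
                 fs, carrier_band[2]))
  structure(list(n_cycles = as.integer(n_cycles),
                 cycle_duration_mean = cycle_duration_mean,
                 cycle_duration_cv = cycle_duration_cv,
                 fs = fs,
                 gain_cv = gain_cv,
                 timing_jitter_sd = timing_jitter_sd,
                 envelope_noise_sd = envelope_noise_sd,
                 carrier_band = carrier_band,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# lognormal draws with a given mean and CV; cv = 0 collapses to the mean
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate per-cycle envelope realizations from a ground-truth model
#'
#' Realizes the generative model envelope = weightings %*% diag(gains) %*%
#' templates for each cycle, with per-cycle lognormal amplitude gains,
#' normally distributed burst-center jitter, and additive envelope noise
#' truncated at zero. Cycle durations are drawn from a lognormal with the
#' configured mean and CV.
#'
#' @param model A [ground_truth_model()].
#' @param config A [simulation_config()]; its `seed` makes the draw
#'   reproducible.
#' @return List with `envelopes` (array n_cycles x muscles x 200),
#'   `durations` (seconds), `gains` (n_cycles x modules matrix of realized
#'   amplitude gains), `model` and `config`.
#' @export
generate_cycle_envelopes <- function(model, config) {
  stopifnot(inherits(model, "ground_truth_model"),
            inherits(config, "simulation_config"))
  if (config$n_cycles < 1) stop("n_cycles must be >= 1")
  set.seed(seed_offset(config$seed, 0L))

  n_cyc <- config$n_cycles
  n_mus <- length(model$muscle_names)
  n_mod <- ncol(model$weightings)

  durations <- rlnorm_mean_cv(n_cyc, config$cycle_duration_mean,
                              config$cycle_duration_cv)
  gains <- matrix(0, n_cyc, n_mod, dimnames = list(NULL, colnames(model$weightings)))
  env <- array(0, dim = c(n_cyc, n_mus, 200),
               dimnames = list(NULL, model$muscle_names, NULL))

  for (ci in seq_len(n_cyc)) {
    g <- rlnorm_mean_cv(n_mod, 1, config$gain_cv)
    gains[ci, ] <- g
    templates <- matrix(0, n_mod, 200)
    for (mi in seq_len(n_mod)) {
      b <- model$bursts[[mi]]
      if (config$timing_jitter_sd > 0) {
        b$center <- (b$center + rnorm(nrow(b), 0, config$timing_jitter_sd)) %% 100
      }
      templates[mi, ] <- burst_template(b)
    }
    e <- model$weightings %*% (g * templates)
    if (config$envelope_noise_sd > 0) {
      peak <- apply(e, 1, max)
      e <- e + matrix(rnorm(n_mus * 200, 0, 1), n_mus, 200) *
        (config$envelope_noise_sd * peak)
      e <- pmax(e, 0)
    }
    env[ci, , ] <- e
  }
  list(envelopes = env, durations = durations, gains = gains,
       model = model, config = config)
}

#' Synthesize a raw recording from cycle envelopes
#'
#' Inverts the envelope pipeline: each cycle's 200-point envelope is resampled
#' to its duration at `fs` and multiplied by a zero-mean, unit-variance noise
#' carrier band-limited to `config$carrier_band`; the product is then
#' band-pass filtered 10--500 Hz, emulating the acquisition chain. The
#' accelerometer channel carries one exponentially damped 15 Hz impact
#' transient per cycle start (amplitude 10 x baseline SD) over a baseline of
#' gait-locked low-frequency sway plus small sensor noise, with a terminal
#' impact marking the end of the last cycle. A
#' short baseline lead-in and tail frame the gait sequence so the first and
#' last impacts are detectable.
#'
#' @param envelopes Cycle envelope array (n_cycles x muscles x 200), e.g.
#'   from [generate_cycle_envelopes()].
#' @param durations Per-cycle durations in seconds.
#' @param config A [simulation_config()].
#' @return A `recording` (see [new_recording()]) with `true_boundaries` set
#'   to the cycle-start sample indices plus the terminal boundary.
#' @export
synthesize_raw <- function(envelopes, durations, config) {
  stopifnot(length(dim(envelopes)) == 3, inherits(config, "simulation_config"))
  if (any(envelopes < 0)) stop("envelopes must be nonnegative")
  set.seed(seed_offset(config$seed, 1L))

  fs <- config$fs
  n_cyc <- dim(envelopes)[1]
  n_mus <- dim(envelopes)[2]
  n_samp <- round(durations * fs)
  if (any(n_samp < 10))
    stop("cycle durations produce fewer than 10 samples per cycle")

  lead_in <- round(0.25 * fs)
  tail_n <- round(0.30 * fs)
  total <- lead_in + sum(n_samp) + tail_n
  starts <- lead_in + c(0, cumsum(n_samp))[seq_len(n_cyc)] + 1L
  terminal <- lead_in + sum(n_samp) + 1L

  # piecewise-resampled envelope time courses, zero outside the gait sequence
  env_full <- matrix(0, n_mus, total)
  for (ci in seq_len(n_cyc)) {
    idx <- starts[ci]:(starts[ci] + n_samp[ci] - 1L)
    src <- seq(0, 1, length.out = 200)
    dst <- seq(0, 1, length.out = n_samp[ci])
    for (mi in seq_len(n_mus)) {
      env_full[mi, idx] <- approx(src, envelopes[ci, mi, ], xout = dst)$y
    }
  }

  # band-limited unit-variance carrier per channel
  emg <- matrix(0, n_mus, total)
  for (mi in seq_len(n_mus)) {
    carrier <- zero_lag_butterworth(rnorm(total), fs, "band", config$carrier_band)
    carrier <- (carrier - mean(carrier)) / sd(carrier)
    emg[mi, ] <- env_full[mi, ] * carrier
  }
  if (any(emg != 0)) {
    emg <- zero_lag_butterworth(emg, fs, "band", c(10, 500))  # acquisition filter
  }
  rownames(emg) <- dimnames(envelopes)[[2]]

  # baseline: gait-locked low-frequency sway (two periods per cycle, as the
  # shank accelerates in swing and stance) plus small wide-band sensor noise;
  # the impact transient is scaled to 10 x the baseline SD
  accel <- rnorm(total, 0, 0.1)
  for (ci in seq_len(n_cyc)) {
    idx <- starts[ci]:(starts[ci] + n_samp[ci] - 1L)
    accel[idx] <- accel[idx] + sin(2 * pi * 2 * (seq_along(idx) - 1) / n_samp[ci])
  }
  impact_amp <- 10 * sd(accel)
  impact_len <- round(0.2 * fs)
  t_imp <- (seq_len(impact_len) - 1) / fs
  waveform <- impact_amp * exp(-t_imp / 0.02) * cos(2 * pi * 15 * t_imp)
  for (s in c(starts, terminal)) {
    idx <- s:min(s + impact_len - 1L, total)
    accel[idx] <- accel[idx] + waveform[seq_along(idx)]
  }

  new_recording(emg = emg, accel = accel, fs = fs,
                true_boundaries = c(starts, terminal),
                config = config)
}

#' Recording container
#'
#' @param emg Muscles x samples matrix (rownames are muscle labels).
#' @param accel Accelerometer vector, same sample count as `emg`.
#' @param fs Sampling rate in Hz.
#' @param true_boundaries Optional strictly increasing cycle-start sample
#'   indices (synthetic recordings only), including the terminal boundary.
#' @param ground_truth Optional [ground_truth_model()] the recording was
#'   generated from.
#' @param config Optional [simulation_config()].
#' @return List of class `recording`.
#' @export
new_recording <- function(emg, accel, fs, true_boundaries = NULL,
                          ground_truth = NULL, config = NULL) {
  emg <- as.matrix(emg)
  if (ncol(emg) != length(accel))
    stop("emg and accel must have equal sample counts")
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(true_boundaries) && any(diff(true_boundaries) <= 0))
    stop("true_boundaries must be strictly increasing")
  structure(list(emg = emg, accel = as.numeric(accel), fs = fs,
                 true_boundaries = true_boundaries,
                 ground_truth = ground_truth, config = config),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$emg), ncol(x$emg), x$fs, ncol(x$emg) / x$fs))
  if (!is.null(x$true_boundaries))
    cat(sprintf("  %d true cycle boundaries\n", length(x$true_boundaries)))
  invisible(x)
}

#' Generate one synthetic walking subject
#'
#' Composes [default_ground_truth()], [generate_cycle_envelopes()] and
#' [synthesize_raw()] into a single recording. With defaults this yields 40
#' step cycles of ~1.1 s (about 44 s of gait, as would fit a 60 s treadmill
#' window), 10 EMG channels at 2000 Hz and one accelerometer channel, with
#' the generating model attached as ground truth.
#'
#' @param config A [simulation_config()].
#' @param model Ground-truth model; defaults to [default_ground_truth()].
#' @return A `recording` with `ground_truth` attached.
#' @examples
#' rec <- generate_subject(simulation_config(seed = 42))
#' rec
#' @export
generate_subject <- function(config = simulation_config(),
                             model = default_ground_truth()) {
  env <- generate_cycle_envelopes(model, config)
  rec <- synthesize_raw(env$envelopes, env$durations, config)
  rec$ground_truth <- model
  rec
}
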