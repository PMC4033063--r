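# Raw recording -> step-cycle envelope set: zero-lag filtering, rectification,
# accelerometer segmentation, time normalization.

#' Zero-lag Butterworth filter
#'
#' Designs an order-`order` Butterworth filter and applies it forward and
#' backward (`signal::filtfilt`), which cancels phase distortion at the cost
#' of squaring the magnitude response (an order-2 design acts as an order-4
#' magnitude response). DC gain is 1 for the low-pass variant.
#'
#' @param x Numeric vector, or muscles x samples matrix filtered row-wise.
#' @param fs Sampling rate in Hz.
#' @param kind `"low"` or `"band"`.
#' @param cutoff Cutoff in Hz (low-pass) or length-2 band edges in Hz.
#' @param order Filter order of the underlying design (default 2).
#' @return Filtered signal, same shape as `x`.
#' @export
zero_lag_butterworth <- function(x, fs, kind = c("low", "band"), cutoff,
                                 order = 2) {
  kind <- match.arg(kind)
  nyq <- fs / 2
  bad <- cutoff[cutoff >= nyq | cutoff <= 0]
  if (length(bad))
    stop(sprintf("cutoff %g Hz is outside (0, Nyquist = %g Hz)", bad[1], nyq))
  if (kind == "band" && length(cutoff) != 2)
    stop("band-pass requires two cutoff frequencies")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n <= 3 * (2 * order + 1))
    stop("signal too short for the requested filter order")
  filt <- if (kind == "low") {
    signal::butter(order, cutoff / nyq, type = "low")
  } else {
    signal::butter(order, cutoff / nyq, type = "pass")
  }
  # odd-reflection padding long enough for the filter transient to settle, so
  # edge effects stay in the discarded extension (forward-backward filtering
  # with zero initial conditions otherwise leaks a startup ramp into the data)
  pad <- min(n - 1L, ceiling(5 * fs / min(cutoff)))
  apply_filtfilt <- function(row) {
    head_ext <- 2 * row[1] - row[(pad + 1L):2L]
    tail_ext <- 2 * row[n] - row[(n - 1L):(n - pad)]
    ext <- signal::filtfilt(filt, c(head_ext, row, tail_ext))
    ext[(pad + 1L):(pad + n)]
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, apply_filtfilt))
    dimnames(out) <- dimnames(x)
    out
  } else {
    apply_filtfilt(x)
  }
}

#' Linear envelope of surface EMG
#'
#' Applies, in order: 20--500 Hz band-pass, full-wave rectification, 10 Hz
#' low-pass; all filters zero-lag Butterworth of order 2. Because
#' forward-backward filtering can undershoot, the result is clipped at zero.
#'
#' @param emg Muscles x samples matrix (or vector).
#' @param fs Sampling rate in Hz; must exceed 1000 so the 500 Hz band edge is
#'   feasible.
#' @param band Analysis band-pass edges in Hz.
#' @param lowpass Envelope smoothing cutoff in Hz.
#' @return Nonnegative envelope, same shape as `emg`.
#' @export
emg_envelope <- function(emg, fs, band = c(20, 500), lowpass = 10) {
  if (fs <= 1000) stop("fs must exceed 1000 Hz")
  bp <- zero_lag_butterworth(emg, fs, "band", band)
  env <- zero_lag_butterworth(abs(bp), fs, "low", lowpass)
  pmax(env, 0)
}

#' Detect step-cycle boundaries from tibial acceleration
#'
#' Low-pass filters the accelerometer trace at 60 Hz and finds heel-strike
#' impacts as local maxima exceeding `median + 3 * MAD-based SD`. A two-pass
#' scheme enforces physiological spacing: provisional peaks give the median
#' inter-peak interval, then peaks closer than half that interval to a larger
#' accepted peak are pruned. A cycle is the span between consecutive
#' boundaries.
#'
#' @param accel Accelerometer vector.
#' @param fs Sampling rate in Hz.
#' @param lowpass Smoothing cutoff in Hz (default 60).
#' @param threshold_k Threshold in robust SDs above the median (default 3).
#' @param min_sep_frac Minimum peak separation as a fraction of the median
#'   provisional inter-peak interval (default 0.5).
#' @return Strictly increasing integer sample indices of detected impacts.
#' @export
detect_cycles <- function(accel, fs, lowpass = 60, threshold_k = 3,
                          min_sep_frac = 0.5) {
  if (length(accel) < 2 * fs) stop("at least 2 s of signal is required")
  x <- zero_lag_butterworth(accel, fs, "low", lowpass)
  if (mad(x) <= .Machine$double.eps * max(abs(x), 1))
    stop("insufficient step events")
  thr <- median(x) + threshold_k * mad(x)
  n <- length(x)
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > thr]
  if (length(cand) < 2) stop("insufficient step events")
  min_sep <- min_sep_frac * median(diff(cand))
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  if (length(keep) < 2) stop("insufficient step events")
  keep
}

#' Time-normalize a cycle segment to a fixed grid
#'
#' Linearly interpolates each channel onto `n_out` points spanning the first
#' through last sample inclusive. Linear interpolation keeps the operator
#' exact on ramps and idempotent on input already of length `n_out`.
#'
#' @param segment Muscles x n_samples matrix (a vector is treated as one
#'   channel).
#' @param n_out Output grid size (default 200, i.e. 0--100% of the cycle in
#'   0.5% steps).
#' @return Muscles x `n_out` matrix.
#' @export
time_normalize <- function(segment, n_out = 200) {
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment)
  if (n < 2) stop("at least 2 samples are required for time normalization")
  xout <- seq(1, n, length.out = n_out)
  out <- t(apply(segment, 1, function(row) approx(seq_len(n), row, xout = xout)$y))
  rownames(out) <- rownames(segment)
  out
}

#' Peak-normalize channels
#'
#' Divides each row by its maximum so every nonzero channel ranges from 0 to
#' 1 in amplitude. All-zero rows are returned unchanged with a warning.
#'
#' @param mat Nonnegative muscles x samples matrix.
#' @return Matrix with every nonzero row's maximum equal to 1.
#' @export
peak_normalize <- function(mat) {
  if (any(mat < 0)) stop("peak_normalize requires nonnegative input")
  rmax <- apply(mat, 1, max)
  zero <- rmax == 0
  if (any(zero)) {
    warning(sprintf("all-zero channel(s) left unchanged: %s",
                    paste(rownames(mat)[zero] %||% which(zero), collapse = ", ")))
    rmax[zero] <- 1
  }
  sweep(mat, 1, rmax, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Step-cycle set container
#'
#' @param cycles Array n_cycles x muscles x 200 of nonnegative envelope
#'   amplitudes on the percent-of-cycle grid.
#' @param muscle_names Ordered channel labels.
#' @param boundaries Sample indices used for segmentation.
#' @param fs Sampling rate of the source recording.
#' @return List of class `step_cycle_set`.
#' @export
step_cycle_set <- function(cycles, muscle_names, boundaries = NULL, fs = NA_real_) {
  stopifnot(length(dim(cycles)) == 3)
  if (dim(cycles)[3] != 200) stop("third dimension must be exactly 200")
  if (any(cycles < 0)) stop("cycle envelopes must be nonnegative")
  dimnames(cycles) <- list(NULL, muscle_names, NULL)
  structure(list(cycles = cycles, muscle_names = muscle_names,
                 boundaries = boundaries, fs = fs),
            class = "step_cycle_set")
}

#' Build a step-cycle set directly from an envelope tensor
#'
#' Bypasses raw synthesis and preprocessing; useful for controlled studies on
#' exactly known envelopes (e.g. zero-variability or noiseless conditions).
#'
#' @param envelopes Array n_cycles x muscles x 200, e.g. the `envelopes`
#'   element of [generate_cycle_envelopes()].
#' @param fs Nominal sampling rate to record.
#' @return A [step_cycle_set()].
#' @export
as_step_cycle_set <- function(envelopes, fs = 2000) {
  step_cycle_set(envelopes, dimnames(envelopes)[[2]] %||% gait_muscles(), fs = fs)
}

#' @export
print.step_cycle_set <- function(x, ...) {
  d <- dim(x$cycles)
  cat(sprintf("<step_cycle_set> %d cycles x %d muscles x %d points\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Preprocess a recording into a step-cycle set
#'
#' Runs the full envelope pipeline ([emg_envelope()]), segments cycles from
#' the accelerometer ([detect_cycles()]) or from supplied true boundaries,
#' and time-normalizes each cycle ([time_normalize()]). Cycles follow the
#' half-open convention `[strike_i, strike_{i+1})`. Peak normalization is
#' deferred to data-structure construction (see [single_cycles()],
#' [averaged_cycles()], [concatenated_cycles()]). When more cycles are
#' available than requested, the first `n_cycles` are retained.
#'
#' @param recording A `recording`.
#' @param n_cycles Number of cycles to retain (default 40).
#' @param use_true_boundaries Use `recording$true_boundaries` instead of the
#'   accelerometer detector.
#' @return A [step_cycle_set()].
#' @export
preprocess_recording <- function(recording, n_cycles = 40,
                                 use_true_boundaries = FALSE) {
  stopifnot(inherits(recording, "recording"))
  env <- emg_envelope(recording$emg, recording$fs)
  boundaries <- if (use_true_boundaries) {
    if (is.null(recording$true_boundaries))
      stop("recording carries no true boundaries")
    recording$true_boundaries
  } else {
    detect_cycles(recording$accel, recording$fs)
  }
  n_avail <- length(boundaries) - 1L
  if (n_avail < n_cycles)
    stop(sprintf("only %d cycles available, %d requested", n_avail, n_cycles))
  boundaries <- boundaries[seq_len(n_cycles + 1L)]
  n_mus <- nrow(env)
  cycles <- array(0, dim = c(n_cycles, n_mus, 200))
  for (ci in seq_len(n_cycles)) {
    seg <- env[, boundaries[ci]:(boundaries[ci + 1L] - 1L), drop = FALSE]
    cycles[ci, , ] <- time_normalize(seg)
  }
  step_cycle_set(cycles, rownames(recording$emg), boundaries, recording$fs)
}
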