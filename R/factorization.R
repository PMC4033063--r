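# NMF with multiplicative updates (Lee-Seung, Frobenius norm), fixed-factor
# variants, VAF reconstruction quality, and random-factor baselines. The
# update loop itself lives in src/nmf_mu.cpp.

MU_EPS <- 1e-12

#' Variance accounted for (VAF)
#'
#' VAF = 1 - SSE/SST with SSE the squared reconstruction error and SST the
#' uncentered total sum of squares (sum of squared data values, pooled over
#' all muscles and samples) — the dominant convention in the synergy
#' literature. Per-muscle values use row-wise sums, so the pooled SSE equals
#' the sum of the per-muscle SSEs.
#'
#' @param X Data matrix (or [envelope_matrix()]).
#' @param Xr Reconstruction, same shape.
#' @param centered Use the centered SST (variance about the row means)
#'   instead of the uncentered convention.
#' @return List of class `vaf_report` with `sse`, `sst`, `vaf` and a
#'   `per_muscle` data frame.
#' @export
vaf <- function(X, Xr, centered = FALSE) {
  X <- as_values(X); Xr <- as_values(Xr)
  if (!all(dim(X) == dim(Xr))) stop("X and Xr must have the same shape")
  ref <- if (centered) X - rowMeans(X) else X
  sse_row <- rowSums((X - Xr)^2)
  sst_row <- rowSums(ref^2)
  sst <- sum(sst_row)
  if (sst == 0) stop("degenerate data: SST is zero")
  per <- data.frame(muscle = rownames(X) %||% paste0("ch", seq_len(nrow(X))),
                    sse = sse_row, sst = sst_row,
                    vaf = ifelse(sst_row > 0, 1 - sse_row / sst_row, NA_real_),
                    row.names = NULL)
  structure(list(sse = sum(sse_row), sst = sst, vaf = 1 - sum(sse_row) / sst,
                 per_muscle = per),
            class = "vaf_report")
}

#' @export
print.vaf_report <- function(x, ...) {
  cat(sprintf("<vaf_report> VAF = %.4f (SSE = %.4g, SST = %.4g)\n",
              x$vaf, x$sse, x$sst))
  invisible(x)
}

check_nmf_input <- function(X) {
  if (any(!is.finite(X))) stop("X contains non-finite values")
  if (any(X < 0)) stop("X must be nonnegative")
  if (all(X == 0)) stop("X is all zero")
  X
}

make_result <- function(X, S, P, best, restarts, seed, canonical = TRUE) {
  if (canonical) {
    cmax <- apply(S, 2, max)
    sc <- ifelse(cmax > 0, cmax, 1)
    S <- sweep(S, 2, sc, "/")
    P <- sweep(P, 1, sc, "*")
  }
  rownames(S) <- rownames(X)
  colnames(S) <- rownames(P) <- paste0("M", seq_len(ncol(S)))
  Xr <- S %*% P
  rep <- vaf(X, Xr)
  structure(list(S = S, P = P, Xr = Xr,
                 vaf_overall = rep$vaf,
                 vaf_per_muscle = stats::setNames(rep$per_muscle$vaf,
                                                  rep$per_muscle$muscle),
                 vaf_report = rep,
                 n_iter = best$n_iter,
                 objective = best$objective,
                 objective_trace = best$objective_trace,
                 restarts = restarts, seed = seed),
            class = "factorization_result")
}

#' @export
print.factorization_result <- function(x, ...) {
  cat(sprintf("<factorization_result> %d muscles x %d modules, T = %d\n",
              nrow(x$S), ncol(x$S), ncol(x$P)))
  cat(sprintf("  VAF = %.4f after %d iterations (best of %d restarts)\n",
              x$vaf_overall, x$n_iter, x$restarts))
  invisible(x)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative muscles x T matrix X as X ~ S P with S (muscles x
#' n_modules, the muscle weightings) and P (n_modules x T, the activation
#' signals), minimizing the squared Frobenius reconstruction error by the
#' Lee-Seung multiplicative update rules. Factors are initialized uniform
#' (0, 1); the best of `restarts` runs (lowest final objective, ties to the
#' earliest restart) is returned. Output is canonically scaled: S columns are
#' max-normalized with compensating row scaling of P, so weighting vectors
#' are comparable across runs.
#'
#' @param X Nonnegative matrix or [envelope_matrix()].
#' @param n_modules Number of modules N (1 <= N <= muscles).
#' @param max_iter Maximum update iterations per restart.
#' @param tol Relative objective-change convergence threshold.
#' @param restarts Number of random restarts.
#' @param seed Optional seed set before drawing initializations.
#' @return Object of class `factorization_result` with elements `S`, `P`,
#'   `Xr = S %*% P`, `vaf_overall`, `vaf_per_muscle`, `n_iter`,
#'   `objective_trace` (squared error per iteration, non-increasing),
#'   `restarts` and `seed`.
#' @examples
#' X <- outer(runif(6), runif(50))
#' fit <- nmf(X, 1, seed = 1)
#' fit$vaf_overall  # rank-1 data: essentially 1
#' @export
nmf <- function(X, n_modules, max_iter = 1000, tol = 1e-6, restarts = 20,
                seed = NULL) {
  Xv <- check_nmf_input(as_values(X))
  M <- nrow(Xv); Tn <- ncol(Xv)
  if (n_modules < 1 || n_modules > M)
    stop("n_modules must be between 1 and the number of muscles")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    W0 <- matrix(runif(M * n_modules), M, n_modules)
    H0 <- matrix(runif(n_modules * Tn), n_modules, Tn)
    fit <- nmf_mu_cpp(Xv, W0, H0, max_iter, tol, TRUE, TRUE, MU_EPS)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  make_result(Xv, best$W, best$H, best, restarts, seed)
}

#' NMF with fixed muscle weightings
#'
#' Optimizes only the activation signals P by multiplicative updates, with
#' the weighting matrix S held fixed at `S_fixed` (returned exactly as
#' supplied). With S fixed the subproblem is convex in P, so a single start
#' suffices by default.
#'
#' @param X Nonnegative matrix or [envelope_matrix()].
#' @param S_fixed Nonnegative muscles x modules weighting matrix.
#' @inheritParams nmf
#' @return A `factorization_result`; `S` is `S_fixed` bit-exactly.
#' @export
nmf_fixed_weightings <- function(X, S_fixed, max_iter = 1000, tol = 1e-6,
                                 restarts = 1, seed = NULL) {
  Xv <- check_nmf_input(as_values(X))
  S_fixed <- as.matrix(S_fixed)
  if (any(S_fixed < 0)) stop("S_fixed must be nonnegative")
  if (nrow(S_fixed) != nrow(Xv)) stop("S_fixed rows must match X rows")
  if (!is.null(seed)) set.seed(seed)
  N <- ncol(S_fixed)
  best <- NULL
  for (r in seq_len(restarts)) {
    H0 <- matrix(runif(N * ncol(Xv)), N, ncol(Xv))
    fit <- nmf_mu_cpp(Xv, S_fixed, H0, max_iter, tol, FALSE, TRUE, MU_EPS)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  make_result(Xv, S_fixed, best$H, best, restarts, seed, canonical = FALSE)
}

#' NMF with fixed activation signals
#'
#' Mirror image of [nmf_fixed_weightings()]: only the weightings S are
#' updated, P is held fixed and returned exactly as supplied.
#'
#' @param X Nonnegative matrix or [envelope_matrix()].
#' @param P_fixed Nonnegative modules x T activation matrix.
#' @inheritParams nmf
#' @return A `factorization_result`; `P` is `P_fixed` bit-exactly.
#' @export
nmf_fixed_activations <- function(X, P_fixed, max_iter = 1000, tol = 1e-6,
                                  restarts = 1, seed = NULL) {
  Xv <- check_nmf_input(as_values(X))
  P_fixed <- as.matrix(P_fixed)
  if (any(P_fixed < 0)) stop("P_fixed must be nonnegative")
  if (ncol(P_fixed) != ncol(Xv)) stop("P_fixed columns must match X columns")
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(P_fixed)
  best <- NULL
  for (r in seq_len(restarts)) {
    W0 <- matrix(runif(nrow(Xv) * N), nrow(Xv), N)
    fit <- nmf_mu_cpp(Xv, W0, P_fixed, max_iter, tol, TRUE, FALSE, MU_EPS)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  make_result(Xv, best$W, P_fixed, best, restarts, seed, canonical = FALSE)
}

#' Random-factor reconstruction baseline
#'
#' Pairs one extracted factor with a randomly generated counterpart to gauge
#' how much reconstruction quality random variability alone achieves. Mode
#' `random_P` keeps the extracted weightings S and randomizes the activation
#' signals; `random_S` keeps the extracted activations P and randomizes the
#' weightings. With `optimize = FALSE` the random factor is uniform (0, 1)
#' scaled so the reconstruction matches the data's mean amplitude; with
#' `optimize = TRUE` it is refined by exactly `n_iter` multiplicative updates
#' against X (making the baseline a fixed-factor fit from a random start).
#'
#' @param X Nonnegative matrix or [envelope_matrix()].
#' @param result A `factorization_result` supplying the extracted factor.
#' @param mode `"random_P"` or `"random_S"`.
#' @param optimize Refine the random factor by multiplicative updates.
#' @param n_iter Number of update iterations when `optimize = TRUE`.
#' @param seed Optional seed.
#' @return List of class `baseline_report` with the achieved `vaf_report`
#'   (element `vaf`), `mode`, `optimize` and the factor pair used.
#' @export
random_baseline <- function(X, result, mode = c("random_P", "random_S"),
                            optimize = FALSE, n_iter = 1000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "factorization_result"))
  Xv <- check_nmf_input(as_values(X))
  if (!is.null(seed)) set.seed(seed)
  N <- ncol(result$S)
  if (mode == "random_P") {
    S <- result$S
    P <- matrix(runif(N * ncol(Xv)), N, ncol(Xv))
  } else {
    S <- matrix(runif(nrow(Xv) * N), nrow(Xv), N)
    P <- result$P
  }
  recon_mean <- mean(S %*% P)
  if (recon_mean > 0) {
    alpha <- mean(Xv) / recon_mean
    if (mode == "random_P") P <- P * alpha else S <- S * alpha
  }
  if (optimize) {
    # tol = 0 forces the literal fixed iteration count
    fit <- nmf_mu_cpp(Xv, S, P, n_iter, 0, mode == "random_S",
                      mode == "random_P", MU_EPS)
    S <- fit$W; P <- fit$H
  }
  structure(list(vaf = vaf(Xv, S %*% P), mode = mode, optimize = optimize,
                 S = S, P = P),
            class = "baseline_report")
}
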