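# Module similarity, best-pair matching, dimensionality selection, and
# averaging of matched factorizations.

#' Normalized scalar-product similarity
#'
#' The scalar product of two nonnegative vectors normalized by the product of
#' their norms (their cosine). Scale-free: comparing shapes, not amplitudes.
#' Ranges from 0 (disjoint support) to 1 (identical shape).
#'
#' @param u,v Nonzero nonnegative vectors of equal length.
#' @return Similarity in [0, 1].
#' @export
module_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined similarity for a zero vector")
  min(1, sum(u * v) / (nu * nv))
}

# all permutations of 1..n as an n!-row matrix (used up to n = 7)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

factor_columns <- function(x, component = "S") {
  if (inherits(x, "factorization_result")) {
    if (component == "S") x$S else t(x$P)
  } else as.matrix(x)
}

#' Match two module sets by best pairs
#'
#' Finds the bijection between the modules of A and the modules of B that
#' maximizes the total normalized scalar-product similarity (a globally
#' optimal assignment, found by exhaustive enumeration; module counts in
#' practice are <= 7). Similarities are reported in A's module order.
#'
#' @param A,B Matrices with modules as columns (weightings, or transposed
#'   activations), or `factorization_result` objects (their S is used).
#' @return List of class `similarity_report` with `pairing` (module i of A
#'   is matched to module `pairing[i]` of B), `similarities` (per matched
#'   pair, in A's order) and `mean_similarity`.
#' @export
match_modules <- function(A, B) {
  A <- factor_columns(A); B <- factor_columns(B)
  if (ncol(A) != ncol(B)) stop("module counts must be equal")
  n <- ncol(A)
  if (n > 7) stop("exhaustive matching supports at most 7 modules")
  simmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    simmat[i, j] <- module_similarity(A[, i], B[, j])
  perms <- all_permutations(n)
  totals <- apply(perms, 1, function(p) sum(simmat[cbind(seq_len(n), p)]))
  best <- as.integer(perms[which.max(totals), ])
  sims <- simmat[cbind(seq_len(n), best)]
  structure(list(pairing = best, similarities = sims,
                 mean_similarity = mean(sims)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> mean similarity %.3f\n", x$mean_similarity))
  cat("  pairing:", paste(seq_along(x$pairing), "->", x$pairing, collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of motor modules
#'
#' Runs [nmf()] for N = 1..n_max and picks the smallest N whose VAF reaches
#' `vaf_threshold` while the curve has flattened (VAF gain from N to N+1
#' below `slope_delta`) — an elbow rule on the VAF curve conjoined with a
#' 90% reconstruction floor. If no N satisfies both, `n_max` is returned
#' with `flagged = TRUE` and a warning.
#'
#' @param X Nonnegative matrix or [envelope_matrix()].
#' @param n_max Largest dimensionality to evaluate (must stay below the
#'   muscle count).
#' @param vaf_threshold Minimum acceptable overall VAF (default 0.90).
#' @param slope_delta Flatness threshold on the VAF increment (default 0.05).
#' @inheritParams nmf
#' @return List of class `dimensionality_selection` with `n`, `vaf_curve`
#'   (named vector over N = 1..n_max) and `flagged`.
#' @export
select_dimensionality <- function(X, n_max = 9, vaf_threshold = 0.90,
                                  slope_delta = 0.05, max_iter = 1000,
                                  tol = 1e-6, restarts = 20, seed = NULL) {
  Xv <- check_nmf_input(as_values(X))
  n_max <- as.integer(n_max)
  if (n_max >= nrow(Xv)) stop("n_max must be below the number of muscles")
  if (!is.null(seed)) set.seed(seed)
  curve <- vapply(seq_len(n_max), function(N) {
    nmf(Xv, N, max_iter = max_iter, tol = tol, restarts = restarts)$vaf_overall
  }, numeric(1))
  names(curve) <- seq_len(n_max)
  ok <- which(curve[-n_max] >= vaf_threshold &
                diff(curve) < slope_delta)
  flagged <- length(ok) == 0
  if (flagged) {
    warning(sprintf(
      "no dimensionality meets VAF >= %.2f with slope change < %.2f; returning n_max = %d",
      vaf_threshold, slope_delta, n_max))
  }
  structure(list(n = if (flagged) n_max else min(ok),
                 vaf_curve = curve, flagged = flagged,
                 vaf_threshold = vaf_threshold, slope_delta = slope_delta),
            class = "dimensionality_selection")
}

#' @export
print.dimensionality_selection <- function(x, ...) {
  cat(sprintf("<dimensionality_selection> N = %d%s\n", x$n,
              if (x$flagged) " (flagged: criteria unmet)" else ""))
  print(round(x$vaf_curve, 4))
  invisible(x)
}

#' Average matched factorizations
#'
#' Aligns each factorization's module order to a reference by best-pair
#' matching on the muscle weightings, then averages S and P element-wise.
#' Used to summarize the 40 single-cycle factorizations of one subject; the
#' natural reference is the factorization of the subject's full 40-cycle
#' concatenation.
#'
#' @param results List of `factorization_result` objects sharing M, N and T.
#' @param reference Factorization whose module order defines the output
#'   order; defaults to the first element of `results`.
#' @return List with mean `S`, mean `P` and `n` (number averaged).
#' @export
average_matched_factorizations <- function(results, reference = results[[1]]) {
  stopifnot(length(results) >= 1)
  dims <- vapply(results, function(r) c(dim(r$S), ncol(r$P)), numeric(3))
  if (any(dims != dims[, 1])) stop("all factorizations must share M, N and T")
  if (!all(dim(reference$S) == dim(results[[1]]$S)))
    stop("reference shape must match the results")
  S_sum <- 0; P_sum <- 0
  for (r in results) {
    p <- match_modules(reference$S, r$S)$pairing
    S_sum <- S_sum + r$S[, p, drop = FALSE]
    P_sum <- P_sum + r$P[p, , drop = FALSE]
  }
  S <- S_sum / length(results)
  P <- P_sum / length(results)
  dimnames(S) <- dimnames(reference$S)
  rownames(P) <- colnames(S)
  list(S = S, P = P, n = length(results))
}
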