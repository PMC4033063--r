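# The three factorization input structures: single cycles (SNG), averaged
# cycles (AVR), concatenated cycles (CNC). Peak normalization is applied
# within each constructed structure, so every nonzero muscle row spans 0-1.

#' Envelope matrix container
#'
#' A muscles x T nonnegative matrix tagged with how it was built: `SNG`
#' (one cycle, T = 200), `AVR` (pointwise mean of k cycles, T = 200) or
#' `CNC` (k cycles side by side, T = 200 k).
#'
#' @param values Nonnegative matrix with muscle rownames.
#' @param structure One of `"SNG"`, `"AVR"`, `"CNC"`.
#' @param k Number of cycles the matrix was built from.
#' @param offset Index of the first cycle used (1-based).
#' @return List of class `envelope_matrix`.
#' @export
envelope_matrix <- function(values, structure = c("SNG", "AVR", "CNC"),
                            k, offset = 1L) {
  structure_tag <- match.arg(structure)
  values <- as.matrix(values)
  if (any(values < 0)) stop("envelope values must be nonnegative")
  expected_t <- if (structure_tag == "CNC") 200L * k else 200L
  if (ncol(values) != expected_t)
    stop(sprintf("%s with k = %d requires %d columns, got %d",
                 structure_tag, k, expected_t, ncol(values)))
  structure(list(values = values, structure_tag = structure_tag,
                 k = as.integer(k), offset = as.integer(offset)),
            class = "envelope_matrix")
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix %s> k = %d, offset = %d, %d x %d\n",
              x$structure_tag, x$k, x$offset, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# strip the container when a plain matrix is wanted
as_values <- function(x) if (inherits(x, "envelope_matrix")) x$values else as.matrix(x)

cycle_matrix <- function(set, ci) {
  m <- set$cycles[ci, , ]
  rownames(m) <- set$muscle_names
  m
}

check_cycle_range <- function(set, k, offset) {
  n <- dim(set$cycles)[1]
  if (k < 1) stop("k must be >= 1")
  if (offset < 1 || offset + k - 1 > n)
    stop(sprintf("cycles %d..%d requested but only 1..%d available",
                 offset, offset + k - 1, n))
}

#' Single-cycle structures (SNG)
#'
#' Each cycle of the set, peak-normalized independently.
#'
#' @param set A [step_cycle_set()].
#' @return List of [envelope_matrix()] objects (tag `SNG`, k = 1), one per
#'   cycle, in cycle order.
#' @export
single_cycles <- function(set) {
  stopifnot(inherits(set, "step_cycle_set"))
  n <- dim(set$cycles)[1]
  if (n < 1) stop("at least one cycle is required")
  lapply(seq_len(n), function(ci) {
    envelope_matrix(peak_normalize(cycle_matrix(set, ci)), "SNG",
                    k = 1L, offset = ci)
  })
}

#' Averaged structure (AVR)
#'
#' Pointwise mean of `k` consecutive cycles on the 200-point grid, then
#' peak-normalized.
#'
#' @param set A [step_cycle_set()].
#' @param k Number of cycles to average.
#' @param offset First cycle index (1-based).
#' @return An [envelope_matrix()] (tag `AVR`).
#' @export
averaged_cycles <- function(set, k, offset = 1L) {
  stopifnot(inherits(set, "step_cycle_set"))
  check_cycle_range(set, k, offset)
  sub <- set$cycles[offset:(offset + k - 1L), , , drop = FALSE]
  m <- apply(sub, c(2, 3), mean)
  rownames(m) <- set$muscle_names
  envelope_matrix(peak_normalize(m), "AVR", k = k, offset = offset)
}

#' Concatenated structure (CNC)
#'
#' `k` consecutive cycles placed side by side in temporal order (width
#' 200 k), then peak-normalized over the whole concatenation.
#'
#' @inheritParams averaged_cycles
#' @return An [envelope_matrix()] (tag `CNC`).
#' @export
concatenated_cycles <- function(set, k, offset = 1L) {
  stopifnot(inherits(set, "step_cycle_set"))
  check_cycle_range(set, k, offset)
  m <- do.call(cbind, lapply(offset:(offset + k - 1L),
                             function(ci) cycle_matrix(set, ci)))
  envelope_matrix(peak_normalize(m), "CNC", k = k, offset = offset)
}
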