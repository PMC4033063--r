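# File formats: recordings as TSV + JSON sidecar, step-cycle sets and
# envelope matrices as TSV, factorizations as TSV pairs, study tables as CSV
# with a JSON run manifest.

required_channels <- function(muscles = gait_muscles()) c("time_s", muscles, "accel")

#' Write a recording as tab-separated text
#'
#' One header row (`time_s`, the 10 muscle labels, `accel`), one row per
#' sample, plus a JSON sidecar (`<path>.json`) holding the sampling rate,
#' generator configuration and true cycle boundaries when present.
#'
#' @param recording A `recording`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  n <- ncol(recording$emg)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$fs,
                   t(recording$emg), accel = recording$accel,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(fs = recording$fs,
               seed = recording$config$seed,
               config = unclass(recording$config),
               true_boundaries = recording$true_boundaries)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording from tab-separated text
#'
#' Expects the format of [write_recording()]. When the JSON sidecar is
#' absent, the sampling rate is inferred as the reciprocal of the median
#' time step.
#'
#' @param path TSV path.
#' @param sidecar Optional sidecar path (default `<path>.json` if present).
#' @return A `recording`.
#' @export
read_recording <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.delim(path, check.names = FALSE)
  need <- required_channels()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("missing required channel(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(diff(df$time_s) <= 0)) stop("time column is not strictly increasing")
  sidecar <- sidecar %||%
    (if (file.exists(paste0(path, ".json"))) paste0(path, ".json") else NULL)
  meta <- if (!is.null(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fs <- meta$fs %||% (1 / median(diff(df$time_s)))
  new_recording(emg = t(as.matrix(df[, gait_muscles()])),
                accel = df$accel, fs = fs,
                true_boundaries = meta$true_boundaries)
}

#' Write / read a step-cycle set
#'
#' Long TSV with columns `cycle`, `muscle`, `p1`..`p200`, plus a JSON
#' sidecar with sampling rate and segmentation boundaries.
#'
#' @param set A [step_cycle_set()].
#' @param path Output TSV path.
#' @return `path` invisibly (writer); a [step_cycle_set()] (reader).
#' @export
write_step_cycle_set <- function(set, path) {
  stopifnot(inherits(set, "step_cycle_set"))
  d <- dim(set$cycles)
  rows <- do.call(rbind, lapply(seq_len(d[1]), function(ci) {
    m <- set$cycles[ci, , ]
    data.frame(cycle = ci, muscle = set$muscle_names, m, check.names = FALSE)
  }))
  names(rows)[-(1:2)] <- paste0("p", seq_len(d[3]))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fs = set$fs, boundaries = set$boundaries,
                            muscle_names = set$muscle_names),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_step_cycle_set
#' @export
read_step_cycle_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  muscles <- meta$muscle_names
  n_cyc <- max(df$cycle)
  cycles <- array(0, dim = c(n_cyc, length(muscles), 200))
  for (ci in seq_len(n_cyc)) {
    sub <- df[df$cycle == ci, ]
    cycles[ci, , ] <- as.matrix(sub[match(muscles, sub$muscle),
                                    paste0("p", 1:200)])
  }
  step_cycle_set(cycles, muscles, boundaries = meta$boundaries, fs = meta$fs)
}

#' Write / read an envelope matrix
#'
#' Muscle-labeled TSV plus a JSON sidecar with the structure tag, k and
#' offset.
#'
#' @param x An [envelope_matrix()].
#' @param path Output TSV path.
#' @return `path` invisibly (writer); an [envelope_matrix()] (reader).
#' @export
write_envelope_matrix <- function(x, path) {
  stopifnot(inherits(x, "envelope_matrix"))
  df <- data.frame(muscle = rownames(x$values), x$values, check.names = FALSE)
  names(df)[-1] <- paste0("t", seq_len(ncol(x$values)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(structure = x$structure_tag, k = x$k,
                            offset = x$offset),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_envelope_matrix
#' @export
read_envelope_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$muscle
  colnames(m) <- NULL
  envelope_matrix(m, meta$structure, k = meta$k, offset = meta$offset)
}

#' Write a factorization result
#'
#' Writes `<prefix>_S.tsv` (muscle weightings), `<prefix>_P.tsv` (activation
#' signals) and `<prefix>_meta.json` (VAF, iterations, restarts, seed).
#'
#' @param fit A `factorization_result`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_factorization <- function(fit, prefix) {
  stopifnot(inherits(fit, "factorization_result"))
  s_df <- data.frame(muscle = rownames(fit$S), fit$S, check.names = FALSE)
  write.table(s_df, paste0(prefix, "_S.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  p_df <- data.frame(module = rownames(fit$P), fit$P, check.names = FALSE)
  write.table(p_df, paste0(prefix, "_P.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(vaf_overall = fit$vaf_overall,
                            vaf_per_muscle = as.list(fit$vaf_per_muscle),
                            n_iter = fit$n_iter, restarts = fit$restarts,
                            seed = fit$seed),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Write study tables and a run manifest
#'
#' Writes the four study tables as CSV plus `manifest.json` recording the
#' package version, master seed, configuration snapshot, timestamps and MD5
#' digests of the written files — enough to reproduce the run bit for bit
#' with the same build.
#'
#' @param tables A `study_tables` object from [run_cohort()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_study_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "study_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("vaf", "similarity", "cross_reconstruction", "baseline")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(tool = "synergait",
                   version = as.character(packageVersion("synergait")),
                   master_seed = tables$seed,
                   n_subjects = tables$n_subjects,
                   config = unclass(tables$config),
                   written = format(Sys.time(), tz = "UTC"),
                   digests = as.list(tools::md5sum(paths)))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
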