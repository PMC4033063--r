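# Orchestration of the three experiments on a (synthetic) cohort:
# structure comparison (VAF), intra-/cross-structure module similarity,
# and fixed-weightings cross-reconstruction; plus random baselines.

#' Factorize all data structures of one subject
#'
#' Runs [nmf()] on every single cycle and on the averaged and concatenated
#' structures for each requested cycle count, reusing one RNG stream so a
#' single seed reproduces the whole set.
#'
#' @param set A [step_cycle_set()].
#' @param ks Cycle counts for AVR/CNC structures.
#' @param n_modules Modules to extract (default 5).
#' @param restarts NMF restarts per factorization.
#' @param seed Optional seed.
#' @param max_iter,tol Convergence settings passed to [nmf()].
#' @return List with `sng` (list over cycles), `avr` and `cnc` (lists named
#'   by k) of `factorization_result` objects.
#' @export
factorize_structures <- function(set, ks = c(2, 3, 5, 10, 20, 40),
                                 n_modules = 5, restarts = 20, seed = NULL,
                                 max_iter = 1000, tol = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  sng_in <- single_cycles(set)
  sng <- lapply(sng_in, nmf, n_modules = n_modules, restarts = restarts,
                max_iter = max_iter, tol = tol)
  avr <- lapply(ks, function(k) nmf(averaged_cycles(set, k),
                                    n_modules = n_modules, restarts = restarts,
                                    max_iter = max_iter, tol = tol))
  cnc <- lapply(ks, function(k) nmf(concatenated_cycles(set, k),
                                    n_modules = n_modules, restarts = restarts,
                                    max_iter = max_iter, tol = tol))
  names(avr) <- names(cnc) <- as.character(ks)
  list(sng = sng, avr = avr, cnc = cnc, ks = ks, n_modules = n_modules)
}

vaf_row <- function(subject, structure, k, cycle, fit) {
  row <- data.frame(subject = subject, structure = structure, k = k,
                    cycle = cycle, n_modules = ncol(fit$S),
                    vaf_overall = fit$vaf_overall)
  pm <- as.list(fit$vaf_per_muscle)
  names(pm) <- paste0("vaf_", names(pm))
  cbind(row, as.data.frame(pm))
}

#' Compare data structures by reconstruction quality
#'
#' For each cycle count k, factorizes the averaged (AVR) and concatenated
#' (CNC) structures at a fixed number of modules, and factorizes each single
#' cycle (SNG); reports overall and per-muscle VAF for every factorization.
#'
#' @inheritParams factorize_structures
#' @param subject Label written into the `subject` column.
#' @param factorizations Optional precomputed [factorize_structures()]
#'   output (avoids refitting when several experiments share one subject).
#' @return Data frame with one row per factorization: columns `subject`,
#'   `structure` (SNG/AVR/CNC), `k`, `cycle` (SNG only), `n_modules`,
#'   `vaf_overall` and per-muscle `vaf_*` columns.
#' @export
run_structure_comparison <- function(set, ks = c(2, 3, 5, 10, 20, 40),
                                     n_modules = 5, restarts = 20,
                                     seed = NULL, subject = 1L,
                                     factorizations = NULL) {
  f <- factorizations %||%
    factorize_structures(set, ks, n_modules, restarts, seed)
  rows <- list()
  for (ci in seq_along(f$sng))
    rows[[length(rows) + 1L]] <- vaf_row(subject, "SNG", 1L, ci, f$sng[[ci]])
  for (k in f$ks) {
    rows[[length(rows) + 1L]] <- vaf_row(subject, "AVR", k, NA_integer_,
                                         f$avr[[as.character(k)]])
    rows[[length(rows) + 1L]] <- vaf_row(subject, "CNC", k, NA_integer_,
                                         f$cnc[[as.character(k)]])
  }
  do.call(rbind, rows)
}

# align a factorization's module order to a reference (match on weightings)
align_to_reference <- function(fit, reference) {
  p <- match_modules(reference$S, fit$S)$pairing
  fit$S <- fit$S[, p, drop = FALSE]
  fit$P <- fit$P[p, , drop = FALSE]
  colnames(fit$S) <- rownames(fit$P) <- colnames(reference$S)
  fit
}

sim_rows <- function(subject, comparison, component, pair, report) {
  data.frame(subject = subject, comparison = comparison,
             component = component,
             module = paste0("M", seq_along(report$similarities)),
             pair = pair, similarity = report$similarities)
}

#' Intra- and cross-structure module similarity
#'
#' Module labels are made comparable by aligning every factorization to one
#' subject-level reference (the full-concatenation factorization). Intra
#' similarities compare factorizations across cycle counts within each
#' structure (for SNG: across all pairs of single cycles); activation-signal
#' similarities are computed where activation lengths match (SNG and AVR,
#' both on the 200-point grid). Cross-structure similarities compare muscle
#' weightings between structures at each cycle count, with the SNG side
#' represented by the matched average of all single-cycle factorizations.
#'
#' @inheritParams run_structure_comparison
#' @return Data frame with columns `subject`, `comparison` (`SNG`, `AVR`,
#'   `CNC` for intra; `SNG-AVR`, `SNG-CNC`, `AVR-CNC` for cross),
#'   `component` (`weightings` or `activations`), `module`, `pair`,
#'   `similarity`.
#' @export
run_intra_and_cross_similarity <- function(set, ks = c(2, 3, 5, 10, 20, 40),
                                           n_modules = 5, restarts = 20,
                                           seed = NULL, subject = 1L,
                                           factorizations = NULL) {
  f <- factorizations %||%
    factorize_structures(set, ks, n_modules, restarts, seed)
  ref <- f$cnc[[as.character(max(f$ks))]]
  sng <- lapply(f$sng, align_to_reference, reference = ref)
  avr <- lapply(f$avr, align_to_reference, reference = ref)
  cnc <- lapply(f$cnc, align_to_reference, reference = ref)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  kpairs <- if (length(f$ks) >= 2) utils::combn(f$ks, 2, simplify = FALSE) else list()
  for (kp in kpairs) {
    a <- as.character(kp[1]); b <- as.character(kp[2])
    lab <- sprintf("k%s-k%s", a, b)
    add(sim_rows(subject, "AVR", "weightings", lab,
                 match_modules(avr[[a]]$S, avr[[b]]$S)))
    add(sim_rows(subject, "CNC", "weightings", lab,
                 match_modules(cnc[[a]]$S, cnc[[b]]$S)))
    add(sim_rows(subject, "AVR", "activations", lab,
                 match_modules(t(avr[[a]]$P), t(avr[[b]]$P))))
  }
  n_sng <- length(sng)
  for (i in seq_len(n_sng - 1L)) for (j in (i + 1L):n_sng) {
    lab <- sprintf("c%d-c%d", i, j)
    add(sim_rows(subject, "SNG", "weightings", lab,
                 match_modules(sng[[i]]$S, sng[[j]]$S)))
    add(sim_rows(subject, "SNG", "activations", lab,
                 match_modules(t(sng[[i]]$P), t(sng[[j]]$P))))
  }
  sng_rep <- average_matched_factorizations(sng, reference = ref)
  for (k in f$ks) {
    kc <- as.character(k)
    lab <- sprintf("k%s", kc)
    add(sim_rows(subject, "SNG-AVR", "weightings", lab,
                 match_modules(sng_rep$S, avr[[kc]]$S)))
    add(sim_rows(subject, "SNG-CNC", "weightings", lab,
                 match_modules(sng_rep$S, cnc[[kc]]$S)))
    add(sim_rows(subject, "AVR-CNC", "weightings", lab,
                 match_modules(avr[[kc]]$S, cnc[[kc]]$S)))
  }
  do.call(rbind, rows)
}

#' Fixed-weightings cross-reconstruction
#'
#' Extracts muscle weightings from first-half structures (cycles 1..k, both
#' CNC and AVR) and uses them to reconstruct second-half concatenations
#' (cycles 21..20+k) and the full concatenation, testing how representative
#' weightings from a short initial stretch of walking are for a longer
#' interval. Two reconstruction rules are reported for every donor/target
#' pair: `free` re-optimizes the activation signals under the fixed donor
#' weightings ([nmf_fixed_weightings()], a convex fit), while `original`
#' combines the donor weightings directly with the target's own extracted
#' activation signals after best-pair module matching — no re-optimization,
#' so any mismatch in the weightings is paid in full. The `free` rule is
#' forgiving (any sensible weightings reconstruct well); the `original` rule
#' is the discriminative one.
#'
#' @inheritParams run_structure_comparison
#' @param ks_weights Cycle counts for the donor (first-half) structures.
#' @param half_offset First cycle of the second half (default 21).
#' @param max_iter,tol Convergence settings passed to the NMF fits.
#' @return Data frame with columns `subject`, `method` (donor structure),
#'   `k_weights`, `target` (`half2_k*` or `full<n>`), `activations`
#'   (`free` or `original`), `vaf`.
#' @export
run_cross_reconstruction <- function(set, ks_weights = c(2, 3, 5, 10, 20),
                                     n_modules = 5, restarts = 20,
                                     seed = NULL, subject = 1L,
                                     half_offset = 21L,
                                     max_iter = 1000, tol = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  n_avail <- dim(set$cycles)[1]
  if (n_avail < half_offset - 1L + max(ks_weights))
    stop(sprintf("cross-reconstruction needs %d cycles, %d available",
                 half_offset - 1L + max(ks_weights), n_avail))
  donors <- list()
  for (k in ks_weights) {
    donors[[paste0("CNC", k)]] <-
      nmf(concatenated_cycles(set, k, 1L), n_modules, restarts = restarts,
          max_iter = max_iter, tol = tol)$S
    donors[[paste0("AVR", k)]] <-
      nmf(averaged_cycles(set, k, 1L), n_modules, restarts = restarts,
          max_iter = max_iter, tol = tol)$S
  }
  targets <- lapply(ks_weights, function(k)
    concatenated_cycles(set, k, half_offset))
  names(targets) <- sprintf("half2_k%d", ks_weights)
  targets[[sprintf("full%d", n_avail)]] <- concatenated_cycles(set, n_avail, 1L)
  target_fits <- lapply(targets, nmf, n_modules = n_modules,
                        restarts = restarts, max_iter = max_iter, tol = tol)
  rows <- list()
  for (k in ks_weights) for (method in c("CNC", "AVR")) {
    S_d <- donors[[paste0(method, k)]]
    for (tn in names(targets)) {
      free_fit <- nmf_fixed_weightings(targets[[tn]], S_d,
                                       max_iter = max_iter, tol = tol)
      tf <- target_fits[[tn]]
      p <- match_modules(tf$S, S_d)$pairing
      orig_vaf <- vaf(targets[[tn]], S_d[, p, drop = FALSE] %*% tf$P)$vaf
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, method = method, k_weights = k,
        target = tn, activations = c("free", "original"),
        vaf = c(free_fit$vaf_overall, orig_vaf))
    }
  }
  do.call(rbind, rows)
}

baseline_rows <- function(subject, structure, X, fit, n_iter = 1000) {
  rows <- list()
  for (mode in c("random_P", "random_S")) for (opt in c(FALSE, TRUE)) {
    b <- random_baseline(X, fit, mode = mode, optimize = opt, n_iter = n_iter)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, structure = structure, mode = mode,
      optimize = opt, vaf = b$vaf$vaf)
  }
  do.call(rbind, rows)
}

#' Run the full study on a synthetic cohort
#'
#' Generates `n_subjects` synthetic walking subjects, preprocesses each into
#' `config$n_cycles` step cycles, and runs the three experiments — structure comparison,
#' intra/cross similarity, and fixed-weightings cross-reconstruction — plus
#' random-factor baselines on the single-cycle, averaged (k = 40) and
#' concatenated (k = 40) structures. Everything is driven from one master
#' seed: subject s uses generator seed `seed + s` and an analysis stream
#' derived from it, so reruns are bit-identical.
#'
#' @param config Cohort-level [simulation_config()]; its `seed` is replaced
#'   per subject.
#' @param n_subjects Number of subjects (default 12).
#' @param ks Cycle counts for the AVR/CNC structures.
#' @param n_modules Modules to extract (default 5).
#' @param restarts NMF restarts per factorization (default 10; the cohort
#'   runs hundreds of factorizations, and 10 restarts keeps the full study
#'   well under a quarter hour on one CPU without measurable loss in best
#'   objective).
#' @param seed Master seed.
#' @param use_true_boundaries Segment from the generator's true boundaries
#'   instead of the accelerometer detector.
#' @return Object of class `study_tables`: list with data frames `vaf`,
#'   `similarity`, `cross_reconstruction`, `baseline`, a `summary` list of
#'   per-condition means and SDs, and the run parameters.
#' @export
run_cohort <- function(config = simulation_config(), n_subjects = 12,
                       ks = c(2, 3, 5, 10, 20, 40), n_modules = 5,
                       restarts = 10, seed = 1L,
                       use_true_boundaries = FALSE) {
  n_cyc <- config$n_cycles
  if (max(ks) > n_cyc)
    stop("ks cannot exceed the configured number of cycles")
  half_offset <- n_cyc %/% 2L + 1L
  ks_weights <- ks[ks <= n_cyc %/% 2L]
  vaf_t <- list(); sim_t <- list(); cross_t <- list(); base_t <- list()
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- seed_offset(seed, s)
    rec <- generate_subject(cfg)
    set <- preprocess_recording(rec, n_cycles = n_cyc,
                                use_true_boundaries = use_true_boundaries)
    f <- factorize_structures(set, ks, n_modules, restarts,
                              seed = seed_offset(seed, 100000L + s))
    vaf_t[[s]] <- run_structure_comparison(set, ks, n_modules, restarts,
                                           subject = s, factorizations = f)
    sim_t[[s]] <- run_intra_and_cross_similarity(set, ks, n_modules, restarts,
                                                 subject = s,
                                                 factorizations = f)
    cross_t[[s]] <- run_cross_reconstruction(set, ks_weights = ks_weights,
                                             n_modules = n_modules,
                                             restarts = restarts,
                                             seed = seed_offset(seed, 200000L + s),
                                             subject = s,
                                             half_offset = half_offset)
    set.seed(seed_offset(seed, 300000L + s))
    k40 <- as.character(max(ks))
    b <- list(baseline_rows(s, "AVR", averaged_cycles(set, max(ks)), f$avr[[k40]]),
              baseline_rows(s, "CNC", concatenated_cycles(set, max(ks)), f$cnc[[k40]]))
    sng_in <- single_cycles(set)
    sng_b <- do.call(rbind, lapply(seq_along(sng_in), function(ci)
      baseline_rows(s, "SNG", sng_in[[ci]], f$sng[[ci]])))
    sng_b <- stats::aggregate(vaf ~ subject + structure + mode + optimize,
                              data = sng_b, FUN = mean)
    base_t[[s]] <- rbind(b[[1]], b[[2]], sng_b[, c("subject", "structure",
                                                   "mode", "optimize", "vaf")])
  }
  tables <- list(vaf = do.call(rbind, vaf_t),
                 similarity = do.call(rbind, sim_t),
                 cross_reconstruction = do.call(rbind, cross_t),
                 baseline = do.call(rbind, base_t))
  tables$summary <- summarize_study(tables)
  tables$seed <- seed
  tables$n_subjects <- n_subjects
  tables$config <- config
  class(tables) <- "study_tables"
  tables
}

mean_sd <- function(df, formula) {
  m <- stats::aggregate(formula, data = df, FUN = mean)
  s <- stats::aggregate(formula, data = df, FUN = sd)
  names(m)[ncol(m)] <- "mean"
  m$sd <- s[[ncol(s)]]
  m
}

#' Descriptive summary of study tables
#'
#' Per-condition means and SDs over subjects, replacing inferential tests
#' with tidy descriptive tables.
#'
#' @param tables List with `vaf`, `similarity`, `cross_reconstruction`,
#'   `baseline` data frames (as produced inside [run_cohort()]).
#' @return List of summary data frames.
#' @export
summarize_study <- function(tables) {
  list(vaf = mean_sd(tables$vaf, vaf_overall ~ structure + k),
       similarity = mean_sd(tables$similarity,
                            similarity ~ comparison + component + module),
       cross_reconstruction = mean_sd(tables$cross_reconstruction,
                                      vaf ~ method + k_weights + target +
                                        activations),
       baseline = mean_sd(tables$baseline, vaf ~ structure + mode + optimize))
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("<study_tables> %d subjects, master seed %d\n",
              x$n_subjects, x$seed))
  cat(sprintf("  vaf: %d rows; similarity: %d; cross-reconstruction: %d; baseline: %d\n",
              nrow(x$vaf), nrow(x$similarity),
              nrow(x$cross_reconstruction), nrow(x$baseline)))
  invisible(x)
}
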