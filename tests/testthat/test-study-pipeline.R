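# Pipeline-level behavior on small, controlled cohorts; the cohort-scale
# directional properties live in test-acceptance.R.

test_that("structure comparison covers the full factorial design", {
  nset <- fixture_noiseless_set(10)
  ks <- c(2, 5, 10)
  f <- factorize_structures(nset, ks, restarts = 5, seed = 1)
  tab <- run_structure_comparison(nset, ks, factorizations = f)
  expect_identical(nrow(tab), 10L + 2L * length(ks))
  expect_identical(sum(tab$structure == "SNG"), 10L)
  expect_true(all(c("vaf_TA", "vaf_GX") %in% names(tab)))
  expect_true(all(tab$vaf_overall <= 1))
})

test_that("identical cycles make the data structures equivalent", {
  nset <- fixture_noiseless_set(10)
  ks <- c(2, 5, 10)

  # with identical cycles the constructed inputs coincide exactly: every AVR
  # equals the single cycle, and CNC blocks repeat it
  one <- single_cycles(nset)[[1]]$values
  for (k in ks) {
    expect_equal(averaged_cycles(nset, k)$values, one, tolerance = 1e-12)
    expect_equal(concatenated_cycles(nset, k)$values[, 1:200], one,
                 tolerance = 1e-12)
  }

  f <- factorize_structures(nset, ks, restarts = 10, seed = 2,
                            max_iter = 4000, tol = 1e-10)
  tab <- run_structure_comparison(nset, ks, factorizations = f)
  # AVR and CNC see the same (repeated) data: equal VAF
  for (k in ks) {
    v_avr <- tab$vaf_overall[tab$structure == "AVR" & tab$k == k]
    v_cnc <- tab$vaf_overall[tab$structure == "CNC" & tab$k == k]
    expect_lt(abs(v_avr - v_cnc), 0.01)
  }

  # factor similarity is bounded only by the non-uniqueness of exact NMF
  # (every fit reaches VAF ~ 1; alternative exact factorizations exist), so
  # the factors agree in shape but not to machine precision
  sims <- run_intra_and_cross_similarity(nset, ks, factorizations = f)
  expect_true(all(sims$similarity > 0.9))
  expect_gt(mean(sims$similarity), 0.98)

  cross <- run_cross_reconstruction(nset, ks_weights = c(2, 3, 5),
                                    restarts = 10, seed = 3, half_offset = 6L,
                                    max_iter = 4000, tol = 1e-10)
  expect_true(all(cross$vaf[cross$activations == "free"] >= 0.99))
  expect_true(all(cross$vaf[cross$activations == "original"] >= 0.95))
})

test_that("similarity table has the expected comparisons and bounds", {
  nset <- fixture_noiseless_set(10)
  ks <- c(2, 5, 10)
  f <- factorize_structures(nset, ks, restarts = 5, seed = 4)
  sims <- run_intra_and_cross_similarity(nset, ks, factorizations = f)
  expect_setequal(unique(sims$comparison),
                  c("SNG", "AVR", "CNC", "SNG-AVR", "SNG-CNC", "AVR-CNC"))
  expect_true(all(sims$similarity >= 0 & sims$similarity <= 1))
  # SNG intra: all unordered cycle pairs, weightings and activations
  expect_identical(sum(sims$comparison == "SNG"), 450L)  # 2 x C(10,2) x 5
  # cross-structure rows: one per structure pair, k and module
  expect_identical(sum(sims$comparison == "AVR-CNC"), length(ks) * 5L)
})

test_that("cross-reconstruction enumerates donors and targets", {
  nset <- fixture_noiseless_set(10)
  cross <- run_cross_reconstruction(nset, ks_weights = c(2, 3), restarts = 5,
                                    seed = 5, half_offset = 6L)
  # methods x donors x targets x activation rules
  expect_identical(nrow(cross), 2L * 2L * 3L * 2L)
  expect_setequal(unique(cross$target), c("half2_k2", "half2_k3", "full10"))
  expect_error(run_cross_reconstruction(nset, ks_weights = c(2, 10),
                                        half_offset = 6L),
               "15 cycles, 10 available")
})

test_that("a small cohort run is complete and reproducible", {
  cfg <- simulation_config(n_cycles = 12)
  run1 <- run_cohort(cfg, n_subjects = 2, ks = c(2, 5), restarts = 4,
                     seed = 99, use_true_boundaries = TRUE)
  run2 <- run_cohort(cfg, n_subjects = 2, ks = c(2, 5), restarts = 4,
                     seed = 99, use_true_boundaries = TRUE)
  for (nm in c("vaf", "similarity", "cross_reconstruction", "baseline"))
    expect_identical(run1[[nm]], run2[[nm]])

  expect_setequal(unique(run1$vaf$subject), 1:2)
  expect_identical(sum(run1$vaf$structure != "SNG"), 2L * 2L * 2L)
  expect_true(all(run1$baseline$vaf <= 1))
  expect_identical(nrow(run1$baseline), 2L * 3L * 4L)

  # end-to-end byte-identical outputs under a fixed master seed
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_study_tables(run1, d1)
  write_study_tables(run2, d2)
  for (nm in c("vaf.csv", "similarity.csv", "cross_reconstruction.csv",
               "baseline.csv"))
    expect_identical(readBin(file.path(d1, nm), "raw", 1e6),
                     readBin(file.path(d2, nm), "raw", 1e6))
})
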