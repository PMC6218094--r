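test_that("fixture generation is deterministic down to the bytes", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_fixtures(d1, seed = 5)
  p2 <- generate_fixtures(d2, seed = 5)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  # a different seed changes the stochastic tables but not the constant ones
  d3 <- withr::local_tempdir()
  p3 <- generate_fixtures(d3, seed = 6)
  expect_identical(readLines(p1[["compounds"]]), readLines(p3[["compounds"]]))
  expect_false(identical(readLines(p1[["calibration"]]),
                         readLines(p3[["calibration"]])))
})

test_that("generator closes the loop with the estimators it feeds", {
  # the prescribed affine law is recoverable
  sim <- simulate_calibration_set(n = 50, slope = 0.8, intercept = 0.030,
                                  sigma = 0.010, seed = 1)
  m <- fit_calibration(sim)
  expect_equal(m$slope, 0.8, tolerance = 0.0625)       # within [0.75, 0.85]
  expect_equal(m$intercept, 0.030, tolerance = 1 / 3)  # within [0.020, 0.040]
  # the planted joint outlier is found
  err <- simulate_outlier_errors(seed = 2)
  z <- tibble::tibble(pair_id = err$pair_id,
                      z_qc = error_zscores(err$err_qc),
                      z_fingerprint = error_zscores(err$err_fingerprint))
  expect_equal(joint_outliers(z)$pair_id, err$pair_id[err$planted])
})

test_that("the synthetic reference mirror reproduces its published summaries", {
  ref <- synthetic_reference_tables()
  d <- ref$experimental
  counts <- table(d$category)
  expect_equal(unname(counts[c("G1", "G2", "G3", "G4")]), c(8, 59, 23, 15),
               ignore_attr = TRUE)
  models <- fit_calibration_by_category(d)
  # the built-in affine systematic error is recovered exactly
  for (g in names(models)) {
    tr <- ref$true_calibration[ref$true_calibration$category == g, ]
    expect_equal(models[[g]]$slope, tr$slope, tolerance = 1e-9, label = g)
    expect_equal(models[[g]]$intercept, tr$intercept_v, tolerance = 1e-9,
                 label = g)
  }
  # per-category calibrated MAE equals the published values to machine precision
  maes <- vapply(models, function(m) m$diagnostics$mae, numeric(1))
  expect_equal(unname(1000 * maes[c("G1", "G2", "G3", "G4")]),
               c(45, 31, 17, 34), tolerance = 1e-9)
})

test_that("toy base energies put each planted couple at its target potential", {
  comp <- simulate_compound_set()
  base <- toy_base_energies()
  ens <- simulate_conformer_ensembles(n_compounds = nrow(comp), seed = 1,
                                      ids = comp$id,
                                      base_energies_hartree = base)
  pairs <- tibble::tibble(pair_id = "C02__C03", substrate_id = "C02",
                          product_id = "C03", category = "G2")
  pred <- predict_potentials(pairs, comp, ens$energies, -1.1675)
  # E0 near its +190 mV anchor (conformer spread shifts it slightly upward)
  expect_equal(pred$e0_v, 0.190, tolerance = 0.05)
  # and the transformed E'm lands near the G2 category mean
  expect_equal(pred$e_prime_m_v, -0.225, tolerance = 0.05)
})

test_that("the full pipeline runs end-to-end on the fixture family", {
  comp <- simulate_compound_set()
  pairs <- toy_pairs(comp)
  ens <- simulate_conformer_ensembles(n_compounds = nrow(comp), seed = 1,
                                      ids = comp$id,
                                      base_energies_hartree = toy_base_energies())
  pred <- predict_potentials(pairs, comp, ens$energies, -1.1675)
  expect_equal(nrow(pred), nrow(pairs))
  expect_true(all(is.finite(pred$e_prime_m_v)))
  expect_equal(unique(pred$method), "qc_raw")
  # raw potentials at identity conditions reproduce E0
  ref_cond <- aqueous_conditions(ph = 0, ionic_strength = 0)
  pred0 <- predict_potentials(pairs, comp, ens$energies, -1.1675, ref_cond)
  no_pka <- c("C02__C03", "C03__C04", "C06__C07", "C08__C10")
  sel <- pred0$pair_id %in% no_pka
  expect_equal(pred0$e_prime_m_v[sel], pred0$e0_v[sel], tolerance = 1e-12)
  # calibration against the synthetic mirror attaches calibrated values
  models <- fit_calibration_by_category(synthetic_reference_tables()$experimental)
  cal <- apply_calibration(pred, models)
  expect_true(all(is.finite(cal$calibrated_v)))
  expect_equal(unique(cal$method), "qc_calibrated")
  # activated-G1 rows get the +250 mV offset on top of the G1 model
  act <- dplyr::mutate(pred[pred$category == "G1", ][1, ],
                       category = "G1-activated")
  cal_act <- apply_calibration(dplyr::bind_rows(pred[pred$category == "G1", ][1, ],
                                                act), models)
  expect_equal(cal_act$calibrated_v[2] - cal_act$calibrated_v[1], 0.250,
               tolerance = 1e-12)
})
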