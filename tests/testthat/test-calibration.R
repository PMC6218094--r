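test_that("two-parameter calibration recovers exact and noisy affine laws", {
  # noise-free affine data: parameters to machine precision
  d <- tibble::tibble(raw = seq(-0.4, -0.1, length.out = 8))
  d$experimental <- 0.8 * d$raw + 0.03
  m <- fit_calibration(d, "G2")
  expect_equal(m$slope, 0.8, tolerance = 1e-10)
  expect_equal(m$intercept, 0.03, tolerance = 1e-10)
  expect_equal(m$diagnostics$mae, 0, tolerance = 1e-12)

  # identity data
  d2 <- tibble::tibble(raw = c(-0.3, -0.2, -0.1),
                       experimental = c(-0.3, -0.2, -0.1))
  m2 <- fit_calibration(d2)
  expect_equal(c(m2$slope, m2$intercept), c(1, 0), tolerance = 1e-12)

  # parameter recovery from the seeded noisy generator
  sim <- simulate_calibration_set(n = 50, slope = 0.8, intercept = 0.030,
                                  sigma = 0.010, seed = 1)
  mr <- fit_calibration(sim, "G2")
  expect_gt(mr$slope, 0.75); expect_lt(mr$slope, 0.85)
  expect_gt(mr$intercept, 0.020); expect_lt(mr$intercept, 0.040)

  # OLS residuals average to ~0
  res <- stats::residuals(mr$fit)
  expect_lt(abs(mean(res)), 1e-10)

  # degenerate inputs are rejected
  expect_error(fit_calibration(tibble::tibble(raw = 1, experimental = 1)),
               "at least 2")
  expect_error(fit_calibration(tibble::tibble(raw = c(1, 1),
                                              experimental = c(1, 2))),
               "zero variance")
})

test_that("calibration models expose broom-style and predict interfaces", {
  sim <- simulate_calibration_set(n = 30, seed = 2)
  m <- fit_calibration(sim, "G3")
  td <- tidy(m)
  expect_equal(td$term, c("slope", "intercept"))
  expect_equal(td$estimate, c(m$slope, m$intercept))
  gl <- glance(m)
  expect_equal(gl$n, 30)
  expect_true(all(c("mae", "pearson_r", "r_squared") %in% names(gl)))
  expect_equal(predict(m, c(-0.2, 0)), m$slope * c(-0.2, 0) + m$intercept)
  # per-category fitting folds activated G1 into G1
  two <- dplyr::bind_rows(
    dplyr::mutate(simulate_calibration_set(n = 10, seed = 3), category = "G1"),
    dplyr::mutate(simulate_calibration_set(n = 6, seed = 4),
                  category = "G1-activated"))
  ms <- fit_calibration_by_category(two)
  expect_named(ms, "G1")
  expect_equal(ms$G1$n, 16)
  # serialized models predict identically after a round-trip
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(ms, path)
  back <- read_calibration(path)
  expect_equal(predict(back$G1, c(-0.3, -0.1)), predict(ms$G1, c(-0.3, -0.1)))
})

test_that("prediction metrics behave like their definitions", {
  ex <- c(-1, 0, 1, 2)
  perfect <- evaluate_predictions(ex, ex)
  expect_equal(unlist(perfect), c(mae = 0, pearson_r = 1, r_squared = 1))
  # the constant mean predictor scores exactly R^2 = 0
  expect_equal(evaluate_predictions(rep(mean(ex), 4), ex)$r_squared, 0)
  # hand-computed example with negative R^2
  e <- evaluate_predictions(c(0, 0, 0, 0), ex)
  expect_equal(e$mae, 1)
  expect_equal(e$r_squared, -0.2, tolerance = 1e-12)
  # constant experimental vector: Pearson NA, no error
  expect_true(is.na(evaluate_predictions(c(1, 2), c(3, 3))$pearson_r))
  # MAE invariant to common shifts; Pearson to affine rescaling
  p <- c(0.1, 0.3, 0.2, 0.5); q <- c(0.2, 0.2, 0.3, 0.4)
  expect_equal(evaluate_predictions(p + 1, q + 1)$mae,
               evaluate_predictions(p, q)$mae)
  expect_equal(evaluate_predictions(3 * p - 2, q)$pearson_r,
               evaluate_predictions(p, q)$pearson_r)
  expect_error(evaluate_predictions(1:3, 1:4), "lengths differ")
})

test_that("error z-scores use the sample estimator and its invariances", {
  expect_equal(error_zscores(c(-2, 2)), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(error_zscores(c(0, 0, 0, 4)), c(-0.5, -0.5, -0.5, 1.5))
  e <- c(0.01, -0.03, 0.02, 0.05)
  expect_equal(error_zscores(e + 0.7), error_zscores(e), tolerance = 1e-12)
  expect_error(error_zscores(c(1, 1, 1)), "zero spread")
  expect_error(error_zscores(0.1), "at least 2")
})

test_that("joint outlier rule flags only cross-method anomalies", {
  z_ok <- tibble::tibble(pair_id = letters[1:5],
                         z_qc = c(-1.5, 0.2, 1.9, -0.3, 0.8),
                         z_fingerprint = c(1.2, -1.8, 0.1, 1.5, -0.6))
  expect_equal(nrow(joint_outliers(z_ok)), 0)

  sim <- simulate_outlier_errors(n = 40, n_outliers = 1, seed = 1)
  z <- tibble::tibble(pair_id = sim$pair_id,
                      z_qc = error_zscores(sim$err_qc),
                      z_fingerprint = error_zscores(sim$err_fingerprint))
  flagged <- joint_outliers(z)
  expect_equal(flagged$pair_id, sim$pair_id[sim$planted])
  # one-method-only outliers are not flagged
  one_sided <- tibble::tibble(pair_id = c("a", "b"),
                              z_qc = c(3.5, 0.1),
                              z_fingerprint = c(0.2, 3.1))
  expect_equal(nrow(joint_outliers(one_sided)), 0)
})
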