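test_that("Welch test matches stats::t.test and reduces to Student's t", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  got <- welch_t_test(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # frozen reference values for this fixture
  expect_equal(got$t, -1.0954451, tolerance = 1e-6)
  expect_equal(got$df, 5.8823529, tolerance = 1e-6)

  # identical groups: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry under swapping
  sw <- welch_t_test(b, a)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p_value, got$p_value)
  # equal variances and sizes: Welch equals the pooled Student formula
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  pooled <- stats::t.test(x, y, var.equal = TRUE)
  w <- welch_t_test(x, y)
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-12)
  expect_error(welch_t_test(c(1, 1), c(1, 2)), "degenerate")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("category summaries report mV with display-only rounding", {
  est <- tibble::tibble(category = c("G2", "G2", "G4"),
                        e_prime_m_v = c(-0.010, -0.020, -0.2237))
  s <- category_summary(est)
  g2 <- s[s$category == "G2", ]
  expect_equal(g2$mean_mv, -15)
  expect_equal(g2$n, 2)
  g4 <- s[s$category == "G4", ]
  expect_equal(g4$rounded_mean_mv, -225)   # -223.7 -> nearest 5
  expect_equal(g4$mean_mv, -223.7)         # unrounded value preserved
  expect_error(category_summary(est[0, ]), "no estimates")
})

test_that("carrier classification partitions the potential axis", {
  nadp <- carrier_profile()
  # window bounds: -380-118.3 and -250+118.3 mV
  expect_equal(classify_vs_carrier(c(-0.550, -0.300, -0.015)),
               c("oxidation_only", "reversible", "reduction_only"))
  # boundary values classify as reversible (closed interval)
  win <- reversibility_window(nadp$e_low, nadp$e_high,
                              nadp$concentration_span)
  expect_equal(classify_vs_carrier(c(win$e_min, win$e_max)),
               c("reversible", "reversible"))
  # exactly one label for any potential; partition property on a grid
  grid <- seq(-0.8, 0.3, by = 0.01)
  labs <- classify_vs_carrier(grid)
  expect_true(all(labs %in% c("oxidation_only", "reversible",
                              "reduction_only")))
  expect_true(all(diff(match(labs, c("oxidation_only", "reversible",
                                     "reduction_only"))) >= 0))
  # data-frame interface appends the class column
  d <- classify_vs_carrier(tibble::tibble(e_prime_m_v = c(-0.6, -0.3)))
  expect_equal(d$carrier_class, c("oxidation_only", "reversible"))
})

test_that("the central-metabolism summary matches the carrier-window logic", {
  cm <- central_metabolism_reference()
  expect_equal(sum(cm$n_reactions), 60)
  # the couples a carrier cannot serve are exactly the named hydrocarbon
  # oxidations (plus the aromatic special cases)
  outside <- cm[cm$direction %in% c("oxidation_only", "oxidation_aromatic") &
                  cm$group == "G4", ]
  expect_match(paste(outside$examples, collapse = " "), "succinate")
  expect_match(paste(outside$examples, collapse = " "), "dihydroorotate")
  # the reversible bulk (activated G1, G2, G3) sits inside the NAD(P)
  # window at the category means
  means_v <- category_reference()
  rev_cats <- c("G1-activated", "G2", "G3")
  cls <- classify_vs_carrier(means_v$mean_e_prime_m_mv[
    means_v$category %in% rev_cats] / 1000)
  expect_true(all(cls == "reversible"))
})

test_that("subgroup comparisons recover planted offsets with Welch p-values", {
  # identical subgroups: delta 0, p 1
  est0 <- tibble::tibble(pair_id = sprintf("p%02d", 1:8),
                         e_prime_m_v = rep(c(-0.2, -0.21, -0.22, -0.23), 2))
  lab0 <- tibble::tibble(pair_id = est0$pair_id,
                         grp = rep(c("a", "b"), each = 4))
  r0 <- subgroup_comparison(est0, lab0, "grp")
  expect_equal(r0$delta_mean_mv, 0)
  expect_equal(r0$p_value, 1)

  # planted 30 mV offset, n = 40 per group, sigma = 20 mV
  n <- 40
  vals <- withr::with_seed(77, c(stats::rnorm(n, -0.200, 0.020),
                                 stats::rnorm(n, -0.230, 0.020)))
  est <- tibble::tibble(pair_id = sprintf("p%03d", seq_len(2 * n)),
                        e_prime_m_v = vals)
  lab <- tibble::tibble(pair_id = est$pair_id,
                        sugar = rep(c("open_chain", "ring_opening"), each = n))
  r <- subgroup_comparison(est, lab, "sugar")
  expect_gt(r$delta_mean_mv, 20); expect_lt(r$delta_mean_mv, 40)
  expect_lt(r$p_value, 0.005)
  # antisymmetry under label swap
  lab_sw <- dplyr::mutate(lab, sugar = rev(sugar))
  r_sw <- subgroup_comparison(est, lab_sw, "sugar")
  expect_equal(r_sw$delta_mean_mv, -r$delta_mean_mv, tolerance = 1e-9)
  # unlabeled estimates are an error naming the ids
  expect_error(subgroup_comparison(est, lab[-1, ], "sugar"), "p001")
})
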