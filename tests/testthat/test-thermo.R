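test_that("extended Debye-Huckel correction matches its closed form", {
  # z^2 = N_H or I = 0 make the correction vanish
  expect_identical(debye_huckel_term(0, 0, 0.25), 0)
  expect_identical(debye_huckel_term(3, 0, 0), 0)
  # hand arithmetic: -2.91482 * 0.5 / 1.8
  expect_equal(debye_huckel_term(1, 0, 0.25), -2.91482 * 0.5 / 1.8,
               tolerance = 1e-12)
  # symmetric in the sign of z
  expect_equal(debye_huckel_term(-2, 1, 0.1), debye_huckel_term(2, 1, 0.1))
  expect_error(debye_huckel_term(1, 0, -0.1), "ionic_strength")
})

test_that("Legendre transform adds the proton and ionic-strength terms", {
  cond0 <- aqueous_conditions(ph = 7, ionic_strength = 0)
  expect_identical(legendre_transform(0, 0, 0, cond0), 0)
  expect_equal(legendre_transform(0, 0, 1, cond0), RT_KJ * log(10) * 7,
               tolerance = 1e-12)
  # identity at the chemical reference state
  ref <- aqueous_conditions(ph = 0, ionic_strength = 0)
  expect_equal(legendre_transform(12.3, -1, 4, ref), 12.3)
  # raising pH by 1 adds exactly N_H * RT ln10
  for (nh in c(1, 3, 6)) {
    d <- legendre_transform(0, 0, nh, aqueous_conditions(ph = 8, ionic_strength = 0)) -
      legendre_transform(0, 0, nh, cond0)
    expect_equal(d, nh * RT_KJ * log(10), tolerance = 1e-12)
  }
})

test_that("pseudoisomer aggregation matches brute-force summation and its bounds", {
  expect_equal(pseudoisomer_energy(7.5), 7.5)
  expect_equal(pseudoisomer_energy(c(3, 3)), 3 - RT_KJ * log(2),
               tolerance = 1e-12)
  # negligible high-energy species
  expect_equal(pseudoisomer_energy(c(0, 50)), brute_pseudoisomer(c(0, 50)),
               tolerance = 1e-15)
  expect_lt(abs(pseudoisomer_energy(c(0, 50))), 1e-8)
  # brute-force agreement, permutation invariance, monotone decrease
  set.seed(11)
  for (i in 1:20) {
    g <- stats::runif(sample(2:6, 1), -30, 30)
    expect_equal(pseudoisomer_energy(g), brute_pseudoisomer(g),
                 tolerance = 1e-10)
    expect_identical(pseudoisomer_energy(g), pseudoisomer_energy(rev(g)))
    expect_lte(pseudoisomer_energy(g), min(g))
    expect_lt(pseudoisomer_energy(c(g, 5)), pseudoisomer_energy(g))
  }
  expect_error(pseudoisomer_energy(numeric()), "non-empty")
})

test_that("transformed potential reproduces the closed-form pH behaviour", {
  cond7 <- aqueous_conditions(ph = 7, ionic_strength = 0)
  ox <- species_ladder(numeric(), z_ms = 0, n_h_ms = 4)
  red <- species_ladder(numeric(), z_ms = 0, n_h_ms = 6)
  # two protons over two electrons: -RT ln10 / F per pH unit
  slope_v <- RT_KJ * log(10) * 1000 / FARADAY
  expect_equal(transformed_potential(0, ox, red, cond7), -slope_v * 7,
               tolerance = 1e-10)
  # identity at pH 0, I 0
  ref <- aqueous_conditions(ph = 0, ionic_strength = 0)
  expect_equal(transformed_potential(-0.123, ox, red, ref), -0.123)
  # a reduced-side pKa exactly at the pH adds RT ln2 / (nF)
  red_pka <- species_ladder(7, z_ms = 0, n_h_ms = 6)
  bump <- transformed_potential(0, ox, red_pka, cond7) -
    transformed_potential(0, ox, red, cond7)
  expect_equal(bump, RT_KJ * log(2) * 1000 / (2 * FARADAY), tolerance = 1e-10)
  expect_equal(1000 * bump, 8.90, tolerance = 1e-2)
  # numerical pH slope at three pH values equals the closed form
  for (m in c(0, 1, 2)) {  # protons transferred
    redm <- species_ladder(numeric(), z_ms = 0, n_h_ms = 4 + m)
    e <- vapply(c(3, 7, 11), function(ph) {
      transformed_potential(0, ox, redm,
                            aqueous_conditions(ph = ph, ionic_strength = 0))
    }, numeric(1))
    expect_equal(diff(e) / 4, rep(-slope_v * m / 2, 2), tolerance = 1e-10)
  }
  # inconsistent ladder stepping is rejected
  bad <- tibble::tibble(dg0 = c(0, 5), z = c(0, -2), n_h = c(4, 3))
  expect_error(transformed_potential(0, bad, red, cond7), "ladder")
})

test_that("millimolar standard state shifts only multi-reactant couples", {
  cond <- aqueous_conditions()  # 1 mM
  # 1:1 couples are unchanged
  for (g in c("G1", "G2", "G4")) {
    expect_equal(millimolar_standard(-0.225, category_co_reactants(g), cond),
                 -0.225)
  }
  # the G3 ammonia substrate: |shift| = RT ln(10^3) / (nF)
  shift <- millimolar_standard(0, category_co_reactants("G3"), cond)
  expect_equal(abs(shift), RT_KJ * 1000 * log(1000) / (2 * FARADAY),
               tolerance = 1e-12)
  expect_equal(1000 * abs(shift), 88.73, tolerance = 1e-2)
  # sign: converting o -> m moves G3 toward the G2 distribution; the two
  # category means coincide at the m state, so starting from the G3 mean
  # displaced upward at the o state the shift must be negative
  expect_lt(shift, 0)
  # c0 = 1 M is the identity for every category
  cond_o <- aqueous_conditions(standard_conc = 1)
  expect_equal(millimolar_standard(-0.3, category_co_reactants("G3"), cond_o),
               -0.3)
})

test_that("activation correction is a flat, invertible +250 mV offset", {
  expect_equal(activation_correction(-0.550), -0.300)
  expect_equal(activation_correction(activation_correction(-0.4), -0.250),
               -0.4)
  # the unrounded thermodynamic shift for 50 kJ/mol over 2 electrons
  expect_equal(1000 * 50 / (2 * FARADAY) * 1000, 259.1, tolerance = 1e-3)
})

test_that("equilibrium ratio follows the Nernst exponential", {
  expect_equal(equilibrium_ratio(-0.3, -0.3), 1)
  expect_equal(equilibrium_ratio(-0.330, -0.268),
               exp(0.062 * 2 * FARADAY / (8.314 * 298.15)), tolerance = 1e-12)
  # reciprocal under swapped arguments
  expect_equal(equilibrium_ratio(-0.31, -0.22) * equilibrium_ratio(-0.22, -0.31),
               1, tolerance = 1e-12)
})

test_that("reversibility window and Keq shift share their kernel", {
  w <- reversibility_window(-0.1, -0.1, concentration_span = 1)
  expect_equal(c(w$e_min, w$e_max), c(-0.1, -0.1))
  expect_equal(1000 * keq_shift_to_potential(1e2), 59.16, tolerance = 1e-2)
  expect_equal(1000 * keq_shift_to_potential(1e4), 118.3, tolerance = 1e-1)
  expect_equal(keq_shift_to_potential(1e4),
               reversibility_window(-0.38, -0.25)$half_width)
  expect_equal(keq_shift_to_potential(1), 0)
  expect_error(keq_shift_to_potential(0), "k")
  expect_error(reversibility_window(-0.1, -0.2), "e_low")
  expect_error(reversibility_window(-0.2, -0.1, concentration_span = 0.5),
               "concentration_span")
})

test_that("volt/energy conversions round-trip to machine precision", {
  for (e in c(-0.55, -0.015, 0.42, 1)) {
    expect_equal(kj_to_volts(volts_to_kj(e)), e, tolerance = 1e-12)
    expect_equal(kj_to_volts(volts_to_kj(e, 1), 1), e, tolerance = 1e-12)
  }
  expect_equal(volts_to_kj(1), -192.970)
})
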