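#' Extended Debye-Huckel energy correction for one protonation species
#'
#' Ionic-strength correction to the transformed standard Gibbs energy of an
#' aqueous species carrying charge `z` and `n_h` hydrogens:
#' \deqn{-\alpha (z^2 - N_H) \sqrt{I} / (1 + B \sqrt{I})}
#' in kJ/mol. The correction vanishes at I = 0 and whenever z^2 = N_H, and is
#' symmetric in the sign of z.
#'
#' @param z integer formal charge of the species (elementary charges).
#' @param n_h integer hydrogen count of the species.
#' @param ionic_strength ionic strength I, mol/L; must be >= 0.
#' @param temperature temperature, K (alpha is parameterized at 298.15 K; the
#'   temperature dependence of alpha is not modeled).
#' @param constants a [redox_constants()] bundle.
#' @return Energy correction, kJ/mol (vectorized over `z`/`n_h`).
#' @examples
#' debye_huckel_term(0, 0, 0.25)   # 0
#' debye_huckel_term(1, 0, 0.25)   # -0.8097 kJ/mol
#' @export
debye_huckel_term <- function(z, n_h, ionic_strength, temperature = 298.15,
                              constants = redox_constants()) {
  if (!is.finite(ionic_strength) || ionic_strength < 0) {
    stop("debye_huckel_term: `ionic_strength` must be >= 0", call. = FALSE)
  }
  sq <- sqrt(ionic_strength)
  -constants$debye_huckel_alpha * (z^2 - n_h) * sq /
    (1 + constants$debye_huckel_b * sq)
}

#' Legendre transform of a protonation species to specified pH and I
#'
#' Transformed standard Gibbs energy of one protonation species relative to
#' the compound's major species at pH 0:
#' \deqn{\Delta G' = \Delta G^0 + N_H RT \ln(10)\, \mathrm{pH} + \mathrm{DH}(z, N_H, I)}
#' where DH is [debye_huckel_term()]. At pH 0 and I 0 the transform is the
#' identity on `dg0`.
#'
#' @param dg0 standard Gibbs energy of the species relative to the pH-0 major
#'   species, kJ/mol (0 for the major species itself).
#' @param z integer charge of the species.
#' @param n_h integer hydrogen count of the species.
#' @param conditions an [aqueous_conditions()] object.
#' @param constants a [redox_constants()] bundle.
#' @return Transformed energy Delta G', kJ/mol (vectorized over species).
#' @examples
#' legendre_transform(0, 0, 1, aqueous_conditions(ph = 7, ionic_strength = 0))
#' # 39.956 kJ/mol = RT ln(10) * 7
#' @export
legendre_transform <- function(dg0, z, n_h, conditions = aqueous_conditions(),
                               constants = redox_constants()) {
  rt <- rt_kj(conditions$temperature, constants)
  dg0 + n_h * rt * log(10) * conditions$ph +
    debye_huckel_term(z, n_h, conditions$ionic_strength,
                      conditions$temperature, constants)
}

#' Pseudoisomer aggregation of transformed species energies
#'
#' A biochemical reactant is an ensemble of protonation species; its group
#' transformed energy is the Boltzmann (log-sum-exp) aggregate
#' \deqn{G' = -RT \ln \sum_j \exp(-\Delta G'_j / RT)}
#' computed overflow-safely by shifting by the minimum energy. The result is
#' always <= the minimum input energy, is permutation-invariant, and can only
#' decrease when a species is added.
#'
#' @param dg_prime numeric vector of transformed species energies, kJ/mol.
#' @param temperature temperature, K.
#' @param constants a [redox_constants()] bundle.
#' @return Group transformed energy, kJ/mol (scalar).
#' @examples
#' pseudoisomer_energy(10)        # 10: single species
#' pseudoisomer_energy(c(0, 0))   # -RT ln 2 = -1.718 kJ/mol
#' @export
pseudoisomer_energy <- function(dg_prime, temperature = 298.15,
                                constants = redox_constants()) {
  if (length(dg_prime) == 0) {
    stop("pseudoisomer_energy: `dg_prime` must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(dg_prime))) {
    stop("pseudoisomer_energy: all energies must be finite", call. = FALSE)
  }
  rt <- rt_kj(temperature, constants)
  g_min <- min(dg_prime)
  g_min - rt * log(sum(exp(-(dg_prime - g_min) / rt)))
}

#' Transformed standard potential of a redox couple from its pH-0 potential
#'
#' Converts the chemical standard reduction potential of the pH-0 major
#' species, `e0_volts`, into the transformed standard potential E'0 at the pH
#' and ionic strength of `conditions`. Each side of the couple is represented
#' by its protonation-species ladder (see [species_ladder()]); the conversion
#' adds only the transform corrections, leaving the electronic-energy-derived
#' part untouched:
#' \deqn{E'^0 = E^0 - [G'_{red} - G'_{ox}] / (nF)}
#' where G' is the [pseudoisomer_energy()] of the Legendre-transformed ladder,
#' each anchored at its own pH-0 major species (Delta G0 = 0).
#'
#' The half-reaction is balanced as ox + H2 -> red (n = 2 by convention), and
#' the hydrogen-electrode reference is pinned at its pH-0 standard state, so
#' the H2 reference contributes no correction; the familiar -RT ln(10)/F x
#' (protons transferred / n) pH slope emerges from the hydrogen-count
#' difference between the reduced and oxidized ladders.
#'
#' @param e0_volts chemical standard potential E0 of the major species at
#'   pH 0, V.
#' @param ox_ladder,red_ladder data frames with columns `dg0`, `z`, `n_h`
#'   describing the oxidized/reduced speciation (from [species_ladder()]).
#' @param conditions an [aqueous_conditions()] object.
#' @param n_electrons electrons transferred (2 for all supported categories).
#' @param constants a [redox_constants()] bundle.
#' @return Transformed standard potential E'0, V.
#' @examples
#' ox <- species_ladder(numeric(), z_ms = 0, n_h_ms = 4)
#' red <- species_ladder(numeric(), z_ms = 0, n_h_ms = 6)
#' transformed_potential(0, ox, red,
#'                       aqueous_conditions(ph = 7, ionic_strength = 0))
#' # -0.4141 V: the -59.16 mV/pH slope over 7 pH units
#' @export
transformed_potential <- function(e0_volts, ox_ladder, red_ladder,
                                  conditions = aqueous_conditions(),
                                  n_electrons = 2,
                                  constants = redox_constants()) {
  if (n_electrons < 1) {
    stop("transformed_potential: `n_electrons` must be >= 1", call. = FALSE)
  }
  check_ladder(ox_ladder, "ox_ladder")
  check_ladder(red_ladder, "red_ladder")
  corr <- function(ladder) {
    gp <- legendre_transform(ladder$dg0, ladder$z, ladder$n_h,
                             conditions, constants)
    pseudoisomer_energy(gp, conditions$temperature, constants)
  }
  delta_corr <- corr(red_ladder) - corr(ox_ladder)   # kJ/mol
  e0_volts - delta_corr * 1000 / (n_electrons * constants$faraday)
}

check_ladder <- function(ladder, name) {
  need <- c("dg0", "z", "n_h")
  if (!is.data.frame(ladder) || !all(need %in% names(ladder)) ||
      nrow(ladder) == 0) {
    stop("transformed_potential: `", name,
         "` must be a non-empty data frame with columns dg0, z, n_h",
         call. = FALSE)
  }
  if (nrow(ladder) > 1) {
    dz <- diff(ladder$z)
    dh <- diff(ladder$n_h)
    if (any(dz != -1) || any(dh != -1)) {
      stop("transformed_potential: `", name, "` is not a consistent ",
           "deprotonation ladder (z and n_h must each step down by 1)",
           call. = FALSE)
    }
  }
  invisible(ladder)
}

#' Adjust a transformed potential to the 1 mM reactant standard state
#'
#' Moves E'0 from the 1 M ("o") to the reactant-concentration standard state
#' of `conditions` (1 mM for the physiological "m" state):
#' \deqn{E'^m = E'^0 - (RT/nF) \sum_i \nu_i \ln(c^0 / 1\,M)}
#' summed over the co-reactants that are adjusted (water, H2 and protons are
#' excluded; the 1:1 ox/red pair itself cancels). For 1:1 couples (G1, G2,
#' G4) this is the identity; for G3 the ammonia substrate (nu = -1) lowers
#' the potential by RT ln(1000)/(nF) = 88.7 mV at the 1 mM state.
#'
#' @param e_prime_volts transformed standard potential E'0, V.
#' @param co_reactants named numeric vector of adjusted co-reactant
#'   stoichiometries (nu > 0 products, nu < 0 substrates), e.g.
#'   `c(NH3 = -1)`; water/H2/protons must not be listed. See
#'   [category_co_reactants()].
#' @param conditions an [aqueous_conditions()] object; `standard_conc` is the
#'   target concentration standard.
#' @param n_electrons electrons transferred.
#' @param constants a [redox_constants()] bundle.
#' @return Potential at the requested concentration standard, V.
#' @examples
#' millimolar_standard(-0.136, category_co_reactants("G3"))  # G3: -88.7 mV shift
#' millimolar_standard(-0.225, category_co_reactants("G2"))  # identity
#' @export
millimolar_standard <- function(e_prime_volts, co_reactants = NULL,
                                conditions = aqueous_conditions(),
                                n_electrons = 2,
                                constants = redox_constants()) {
  if (is.null(co_reactants) || length(co_reactants) == 0) {
    return(e_prime_volts)
  }
  rt <- rt_kj(conditions$temperature, constants)          # kJ/mol
  adj <- sum(co_reactants) * log(conditions$standard_conc / 1)
  e_prime_volts - rt * adj * 1000 / (n_electrons * constants$faraday)
}

#' Implied co-reactant stoichiometry of an oxidoreductase category
#'
#' Reductions are balanced as ox + H2 -> red plus the category's implied
#' co-reactants. Only co-reactants subject to the concentration-standard
#' adjustment are returned (water, H2 and protons are excluded by
#' convention): G3 (carbonyl to amine) consumes one ammonia; G1, G2 and G4
#' are 1:1 couples with no adjusted co-reactant.
#'
#' @param category one of "G1", "G1-activated", "G2", "G3", "G4".
#' @return Named numeric vector of stoichiometries (possibly empty);
#'   nu < 0 for substrates.
#' @examples
#' category_co_reactants("G3")  # c(NH3 = -1)
#' @export
category_co_reactants <- function(category) {
  category <- match.arg(category, redox_categories())
  if (category == "G3") c(NH3 = -1) else stats::setNames(numeric(0), character(0))
}

#' @rdname category_co_reactants
#' @export
redox_categories <- function() {
  c("G1", "G1-activated", "G2", "G3", "G4")
}

#' Activation correction for carboxylic-acid reductions
#'
#' Activated carboxylic acids (thioesters, phosphoanhydrides) release the
#' hydrolysis energy of the activating group (~50 kJ/mol) upon reduction,
#' uniformly raising the reduction potential of the G1 distribution. The
#' correction is a flat configurable offset, +250 mV by default (the
#' unrounded value for 50 kJ/mol and n = 2 is 259.1 mV; the conventional
#' rounded constant is the default).
#'
#' @param e_m_volts unactivated G1 potential(s) E'm, V.
#' @param offset_volts activation offset, V (default 0.250).
#' @return Activated-G1 potential(s), V.
#' @examples
#' activation_correction(-0.550)  # -0.300
#' @export
activation_correction <- function(e_m_volts, offset_volts = 0.250) {
  e_m_volts + offset_volts
}

#' Equilibrium concentration ratio imposed by a carrier on a redox couple
#'
#' At equilibrium with an electron carrier held at potential `e_carrier`, the
#' reduced:oxidized concentration ratio of a couple with standard potential
#' `e_couple` is
#' \deqn{[red]/[ox] = \exp(-(E_{carrier} - E'^m)\, nF / RT).}
#' For NAD(P) at -330 mV against the mean carbonyl-reduction couple at
#' -225 mV this is ~3500: carbonyls are kept far below their hydroxycarbons.
#'
#' @param e_carrier carrier potential, V.
#' @param e_couple couple transformed potential E'm, V.
#' @param n_electrons electrons transferred.
#' @param temperature temperature, K.
#' @param constants a [redox_constants()] bundle.
#' @return Dimensionless ratio (vectorized).
#' @examples
#' equilibrium_ratio(-0.330, -0.225)  # 3546
#' @export
equilibrium_ratio <- function(e_carrier, e_couple, n_electrons = 2,
                              temperature = 298.15,
                              constants = redox_constants()) {
  if (n_electrons < 1) {
    stop("equilibrium_ratio: `n_electrons` must be >= 1", call. = FALSE)
  }
  rt <- constants$R * temperature
  exp(-(e_carrier - e_couple) * n_electrons * constants$faraday / rt)
}

#' Reversibility window of an electron carrier
#'
#' A couple can be driven in both directions by a carrier whose physiological
#' potential lies in `[e_low, e_high]` provided the couple's potential can be
#' brought into that range by concentration adjustment. With metabolite
#' concentrations spanning a factor `concentration_span` (default 10^4, i.e.
#' 1 uM to 10 mM), the couple potential can be offset by up to
#' \deqn{w = RT \ln(\mathrm{span}) / (nF)}
#' (118.3 mV for span 10^4 and n = 2), widening the carrier range to
#' `(e_low - w, e_high + w)`.
#'
#' @param e_low,e_high carrier potential range, V (`e_low <= e_high`).
#' @param concentration_span ratio of maximal to minimal metabolite
#'   concentration; must be >= 1.
#' @param n_electrons electrons transferred.
#' @param temperature temperature, K.
#' @param constants a [redox_constants()] bundle.
#' @return A tibble with columns `e_min`, `e_max`, `half_width` (all V).
#' @examples
#' reversibility_window(-0.380, -0.250)  # approximately (-0.498, -0.132)
#' @export
reversibility_window <- function(e_low, e_high, concentration_span = 1e4,
                                 n_electrons = 2, temperature = 298.15,
                                 constants = redox_constants()) {
  if (any(e_low > e_high)) {
    stop("reversibility_window: `e_low` must be <= `e_high`", call. = FALSE)
  }
  if (!is.finite(concentration_span) || concentration_span < 1) {
    stop("reversibility_window: `concentration_span` must be >= 1",
         call. = FALSE)
  }
  w <- keq_shift_to_potential(concentration_span, n_electrons, temperature,
                              constants)
  tibble::tibble(e_min = e_low - w, e_max = e_high + w, half_width = w)
}

#' Potential shift equivalent to an equilibrium constant
#'
#' The potential offset corresponding to a dimensionless equilibrium constant
#' K in an n-electron couple: RT ln(K)/(nF). Used both for the reversibility
#' half-width (K = concentration span) and for interpreting conformational
#' pre-equilibria (e.g. sugar ring opening with K ~ 350 shifts the apparent
#' potential by ~75 mV).
#'
#' @param k equilibrium constant; must be > 0.
#' @param n_electrons electrons transferred; must be >= 1.
#' @param temperature temperature, K.
#' @param constants a [redox_constants()] bundle.
#' @return Potential shift, V.
#' @examples
#' 1000 * keq_shift_to_potential(350)  # 75.25 mV
#' @export
keq_shift_to_potential <- function(k, n_electrons = 2, temperature = 298.15,
                                   constants = redox_constants()) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("keq_shift_to_potential: `k` must be > 0", call. = FALSE)
  }
  if (n_electrons < 1) {
    stop("keq_shift_to_potential: `n_electrons` must be >= 1", call. = FALSE)
  }
  constants$R * temperature * log(k) / (n_electrons * constants$faraday)
}
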