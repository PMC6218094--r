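#' Physical constants for redox thermodynamics
#'
#' Bundle of the physical constants used throughout the package. All values are
#' strictly positive and the returned object should be treated as immutable;
#' every function that needs a constant takes one of these bundles so that a
#' non-default parameterization (e.g. different Debye-Huckel coefficients)
#' threads through the whole pipeline consistently.
#'
#' @param R gas constant, J mol^-1 K^-1.
#' @param faraday Faraday constant, C mol^-1.
#' @param hartree_kj conversion factor, kJ mol^-1 per Hartree.
#' @param debye_huckel_alpha extended Debye-Huckel alpha at 298.15 K,
#'   kJ mol^-1 per sqrt(mol/L) (Alberty's standard parameterization).
#' @param debye_huckel_b extended Debye-Huckel B, sqrt(mol/L)^-1.
#'
#' @return A list of class `redox_constants`.
#' @examples
#' redox_constants()
#' @export
redox_constants <- function(R = 8.314,
                            faraday = 96485,
                            hartree_kj = 2625.50,
                            debye_huckel_alpha = 2.91482,
                            debye_huckel_b = 1.6) {
  vals <- c(R = R, faraday = faraday, hartree_kj = hartree_kj,
            debye_huckel_alpha = debye_huckel_alpha,
            debye_huckel_b = debye_huckel_b)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("redox_constants: all constants must be finite and strictly positive; ",
         "offending: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.list(vals), class = "redox_constants")
}

#' Aqueous conditions for the transformed standard state
#'
#' The biochemical standard state used throughout: pH, ionic strength,
#' temperature and the reactant standard concentration. The default is the
#' physiological "m" convention: pH 7, I = 0.25 M, T = 298.15 K and reactant
#' concentrations standardized to 1 mM (better matching typical metabolite
#' levels than the chemist's 1 M). Set `standard_conc = 1` for the "o" state.
#'
#' @param ph solution pH (dimensionless).
#' @param ionic_strength ionic strength I, mol/L; must be >= 0.
#' @param temperature temperature, K; must be > 0.
#' @param standard_conc reactant standard concentration c0, mol/L; 0.001 for
#'   the "m" state, 1 for the "o" state.
#'
#' @return A list of class `aqueous_conditions`.
#' @examples
#' aqueous_conditions()                    # E'm state: pH 7, I 0.25 M, 1 mM
#' aqueous_conditions(ph = 0, ionic_strength = 0)  # chemical reference state
#' @export
aqueous_conditions <- function(ph = 7,
                               ionic_strength = 0.25,
                               temperature = 298.15,
                               standard_conc = 0.001) {
  if (!is.finite(ph)) stop("aqueous_conditions: `ph` must be finite", call. = FALSE)
  if (!is.finite(ionic_strength) || ionic_strength < 0) {
    stop("aqueous_conditions: `ionic_strength` must be >= 0", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("aqueous_conditions: `temperature` must be > 0", call. = FALSE)
  }
  if (!is.finite(standard_conc) || standard_conc <= 0) {
    stop("aqueous_conditions: `standard_conc` must be > 0", call. = FALSE)
  }
  structure(list(ph = ph, ionic_strength = ionic_strength,
                 temperature = temperature, standard_conc = standard_conc),
            class = "aqueous_conditions")
}

#' @export
print.aqueous_conditions <- function(x, ...) {
  cat(sprintf("<aqueous_conditions> pH %.4g, I %.4g M, T %.6g K, c0 %.4g M\n",
              x$ph, x$ionic_strength, x$temperature, x$standard_conc))
  invisible(x)
}

# RT in kJ/mol at temperature T
rt_kj <- function(temperature, constants = redox_constants()) {
  constants$R * temperature / 1000
}

#' Convert between volts and kJ/mol for an n-electron transfer
#'
#' `volts_to_kj()` returns the Gibbs-energy equivalent -n F E (kJ/mol) of a
#' reduction potential; `kj_to_volts()` inverts it. The two compose to the
#' identity to machine precision.
#'
#' @param e_volts potential, V.
#' @param g_kj Gibbs energy, kJ/mol.
#' @param n_electrons electrons transferred (default 2).
#' @param constants a [redox_constants()] bundle.
#' @return A numeric vector.
#' @examples
#' volts_to_kj(1, n_electrons = 2)   # -192.97 kJ/mol
#' kj_to_volts(volts_to_kj(0.42))    # 0.42
#' @export
volts_to_kj <- function(e_volts, n_electrons = 2, constants = redox_constants()) {
  -n_electrons * constants$faraday * e_volts / 1000
}

#' @rdname volts_to_kj
#' @export
kj_to_volts <- function(g_kj, n_electrons = 2, constants = redox_constants()) {
  -g_kj * 1000 / (n_electrons * constants$faraday)
}

#' Round to the nearest multiple of a base
#'
#' Display-layer rounding used when reporting potentials in mV (nearest
#' multiple of 5 by convention). Never applied to internal values.
#'
#' @param x numeric vector.
#' @param base rounding base (default 5).
#' @return `x` rounded to the nearest multiple of `base`.
#' @examples
#' round_to_nearest(118.3)  # 120
#' round_to_nearest(-223.7) # -225
#' @export
round_to_nearest <- function(x, base = 5) {
  base * round(x / base)
}
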