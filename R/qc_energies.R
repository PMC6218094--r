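#' Boltzmann average of conformer electronic energies
#'
#' Thermal average of an ensemble of conformer electronic energies (Hartree)
#' at temperature T, with weights
#' \deqn{w_i \propto \exp(-(E_i - E_{min})\, C / RT)}
#' where C converts Hartree to kJ/mol. Shifting by the minimum keeps the
#' weights numerically stable for widely separated conformers. The result
#' always lies within `[min(E), max(E)]`, tends to the minimum as T -> 0 and
#' to the arithmetic mean as T -> infinity.
#'
#' @param energies_hartree numeric vector of conformer electronic energies,
#'   Hartree; must be non-empty and finite. Duplicates are kept (they do not
#'   change the weighted mean).
#' @param temperature temperature, K.
#' @param constants a [redox_constants()] bundle.
#' @return Boltzmann-averaged electronic energy, Hartree.
#' @examples
#' boltzmann_average(c(-1.0, -1.0))  # -1.0: equal weights
#' @export
boltzmann_average <- function(energies_hartree, temperature = 298.15,
                              constants = redox_constants()) {
  if (length(energies_hartree) == 0) {
    stop("boltzmann_average: `energies_hartree` must be non-empty",
         call. = FALSE)
  }
  if (any(!is.finite(energies_hartree))) {
    stop("boltzmann_average: all energies must be finite", call. = FALSE)
  }
  rt <- rt_kj(temperature, constants)                    # kJ/mol
  rel <- (energies_hartree - min(energies_hartree)) * constants$hartree_kj
  w <- exp(-rel / rt)
  sum(energies_hartree * w) / sum(w)
}

#' Boltzmann-averaged energies for a conformer-energy table
#'
#' Data-frame interface over [boltzmann_average()]: groups a long
#' conformer-energy table (see [read_energy_table()]) by compound and model
#' chemistry and averages each ensemble.
#'
#' @param energies a data frame with columns `compound_id`,
#'   `model_chemistry`, `energy_hartree` (one row per conformer).
#' @param temperature temperature, K.
#' @param constants a [redox_constants()] bundle.
#' @return A tibble with columns `compound_id`, `model_chemistry`,
#'   `n_conformers`, `energy_hartree` (the ensemble average).
#' @export
boltzmann_means <- function(energies, temperature = 298.15,
                            constants = redox_constants()) {
  stopifnot(is.data.frame(energies),
            all(c("compound_id", "model_chemistry", "energy_hartree") %in%
                  names(energies)))
  energies |>
    dplyr::group_by(.data$compound_id, .data$model_chemistry) |>
    dplyr::summarise(
      n_conformers = dplyr::n(),
      energy_hartree = boltzmann_average(.data$energy_hartree, temperature,
                                         constants),
      .groups = "drop"
    )
}

#' Reaction electronic-energy differences referenced to molecular hydrogen
#'
#' For each redox pair (balanced as ox + H2 -> red), the electronic reaction
#' energy is
#' \deqn{\Delta E = \langle E_{red} \rangle - \langle E_{ox} \rangle - E_{H_2}}
#' where the angle brackets are Boltzmann ensemble averages and E_H2 is the
#' hydrogen electronic energy computed with the same model chemistry
#' (realizing the standard-hydrogen-electrode reference). Input energies are
#' Hartree; the result is reported in kJ/mol.
#'
#' @param pairs a data frame with columns `pair_id`, `substrate_id`
#'   (oxidized) and `product_id` (reduced).
#' @param energies a conformer-energy table (columns `compound_id`,
#'   `model_chemistry`, `energy_hartree`).
#' @param h2_reference a data frame with columns `model_chemistry`,
#'   `energy_hartree` giving the H2 electronic energy per model chemistry,
#'   or a single number when only one model chemistry is in play.
#' @param model_chemistry which model chemistry tag to use; default the
#'   single tag present in `energies` (an error if several are present).
#' @param temperature temperature, K (Boltzmann weighting).
#' @param constants a [redox_constants()] bundle.
#' @return A tibble: `pair_id`, `substrate_id`, `product_id`,
#'   `model_chemistry`, `delta_e_kj`.
#' @export
reaction_delta_electronic <- function(pairs, energies, h2_reference,
                                      model_chemistry = NULL,
                                      temperature = 298.15,
                                      constants = redox_constants()) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "substrate_id", "product_id") %in% names(pairs)))
  if (is.null(model_chemistry)) {
    tags <- unique(energies$model_chemistry)
    if (length(tags) != 1) {
      stop("reaction_delta_electronic: several model chemistries present (",
           paste(tags, collapse = ", "),
           "); pass `model_chemistry` explicitly", call. = FALSE)
    }
    model_chemistry <- tags
  }
  if (is.numeric(h2_reference)) {
    h2_reference <- tibble::tibble(model_chemistry = model_chemistry,
                                   energy_hartree = h2_reference)
  }
  h2_row <- h2_reference[h2_reference$model_chemistry == model_chemistry, ]
  if (nrow(h2_row) != 1) {
    stop("reaction_delta_electronic: no H2 reference energy for model ",
         "chemistry '", model_chemistry, "'", call. = FALSE)
  }
  e_h2 <- h2_row$energy_hartree

  means <- boltzmann_means(
    energies[energies$model_chemistry == model_chemistry, , drop = FALSE],
    temperature, constants
  )
  lookup <- stats::setNames(means$energy_hartree, means$compound_id)
  missing_ids <- setdiff(unique(c(pairs$substrate_id, pairs$product_id)),
                         names(lookup))
  if (length(missing_ids) > 0) {
    stop("reaction_delta_electronic: no conformer ensemble under model ",
         "chemistry '", model_chemistry, "' for compound(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  delta_hartree <- lookup[pairs$product_id] - lookup[pairs$substrate_id] - e_h2
  tibble::tibble(
    pair_id = pairs$pair_id,
    substrate_id = pairs$substrate_id,
    product_id = pairs$product_id,
    model_chemistry = model_chemistry,
    delta_e_kj = unname(delta_hartree) * constants$hartree_kj
  )
}

#' Electronic reaction energy to standard reduction potential
#'
#' The standard reduction potential of the pH-0 major-species couple is taken
#' as directly proportional to the electronic reaction energy:
#' \deqn{E^0 = -\Delta E_{Electronic} / (nF).}
#' A more exergonic reduction (more negative Delta E) maps to a higher
#' potential. Rovibrational thermochemistry is deliberately omitted here; the
#' downstream per-category linear calibration absorbs the resulting
#' systematic offset.
#'
#' @param delta_e_kj electronic reaction energy, kJ/mol (vectorized).
#' @param n_electrons electrons transferred; must be >= 1.
#' @param constants a [redox_constants()] bundle.
#' @return Standard potential E0 of the major species at pH 0, V.
#' @examples
#' electronic_to_potential(-192.970)  # +1 V for n = 2
#' @export
electronic_to_potential <- function(delta_e_kj, n_electrons = 2,
                                    constants = redox_constants()) {
  if (n_electrons < 1) {
    stop("electronic_to_potential: `n_electrons` must be >= 1", call. = FALSE)
  }
  -delta_e_kj * 1000 / (n_electrons * constants$faraday)
}
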