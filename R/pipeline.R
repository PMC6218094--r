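#' End-to-end potential prediction for a set of redox pairs
#'
#' Chains the whole prediction pipeline: Boltzmann-average the conformer
#' ensembles, reference the reaction electronic energies to molecular
#' hydrogen, convert to the chemical standard potential E0 of the pH-0 major
#' species, apply the speciation/Legendre-transform correction to E'0 at the
#' requested pH and ionic strength, and adjust co-reactant concentrations to
#' the reactant standard state (E'm for the default 1 mM convention; the G3
#' ammonia substrate is the one category with a nonzero adjustment).
#'
#' @param pairs a pair table (`pair_id`, `substrate_id`, `product_id`,
#'   `category`; see [match_pairs()]).
#' @param compounds a compound table (see [read_compound_table()]) carrying
#'   charge, hydrogen counts and pKa ladders.
#' @param energies a conformer-energy table (see [read_energy_table()]).
#' @param h2_reference H2 electronic energy (Hartree), scalar or per-model
#'   chemistry table (see [reaction_delta_electronic()]).
#' @param conditions an [aqueous_conditions()] object.
#' @param model_chemistry optional model-chemistry tag selection.
#' @param constants a [redox_constants()] bundle.
#' @return A tibble with one row per pair: `pair_id`, `substrate_id`,
#'   `product_id`, `category`, `delta_e_kj`, `e0_v`, `e_prime_o_v`,
#'   `e_prime_m_v`, `method` (`"qc_raw"`), plus the conditions as columns
#'   `ph`, `ionic_strength`, `temperature`, `standard_conc`.
#' @export
predict_potentials <- function(pairs, compounds, energies, h2_reference,
                               conditions = aqueous_conditions(),
                               model_chemistry = NULL,
                               constants = redox_constants()) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "substrate_id", "product_id", "category") %in%
                  names(pairs)))
  deltas <- reaction_delta_electronic(pairs, energies, h2_reference,
                                      model_chemistry,
                                      conditions$temperature, constants)
  e0 <- electronic_to_potential(deltas$delta_e_kj, 2, constants)

  pka_list <- compound_pka_list(compounds)
  names(pka_list) <- compounds$id
  ladder_of <- function(id) {
    i <- match(id, compounds$id)
    if (is.na(i)) {
      stop("predict_potentials: compound '", id,
           "' missing from the compound table", call. = FALSE)
    }
    species_ladder(pka_list[[i]], compounds$charge[i],
                   compounds$n_hydrogens[i], conditions$temperature,
                   constants = constants)
  }
  e_prime_o <- vapply(seq_len(nrow(pairs)), function(i) {
    transformed_potential(e0[i],
                          ladder_of(pairs$substrate_id[i]),
                          ladder_of(pairs$product_id[i]),
                          conditions, 2, constants)
  }, numeric(1))
  e_prime_m <- vapply(seq_len(nrow(pairs)), function(i) {
    millimolar_standard(e_prime_o[i],
                        category_co_reactants(pairs$category[i]),
                        conditions, 2, constants)
  }, numeric(1))

  tibble::tibble(
    pair_id = pairs$pair_id,
    substrate_id = pairs$substrate_id,
    product_id = pairs$product_id,
    category = pairs$category,
    delta_e_kj = deltas$delta_e_kj,
    e0_v = e0,
    e_prime_o_v = e_prime_o,
    e_prime_m_v = e_prime_m,
    method = "qc_raw",
    ph = conditions$ph,
    ionic_strength = conditions$ionic_strength,
    temperature = conditions$temperature,
    standard_conc = conditions$standard_conc
  )
}

#' Apply per-category calibration models to raw predictions
#'
#' Adds a `calibrated_v` column (and flips `method` to `"qc_calibrated"`)
#' by applying each row's category model. `"G1-activated"` rows use the G1
#' model; when `activation_offset` is not `NULL`, the activation correction
#' is applied on top for those rows.
#'
#' @param predictions a tibble from [predict_potentials()] (needs `category`
#'   and `e_prime_m_v`).
#' @param models a named list of [fit_calibration()] models (names are
#'   categories), as from [fit_calibration_by_category()].
#' @param activation_offset activation offset in V applied to
#'   `"G1-activated"` rows after calibration (default 0.250); `NULL` to
#'   skip.
#' @return `predictions` with added `calibrated_v`, `method` set to
#'   `"qc_calibrated"`.
#' @export
apply_calibration <- function(predictions, models, activation_offset = 0.250) {
  stopifnot(is.data.frame(predictions),
            all(c("category", "e_prime_m_v") %in% names(predictions)))
  model_cat <- ifelse(predictions$category == "G1-activated", "G1",
                      predictions$category)
  missing_models <- setdiff(unique(model_cat), names(models))
  if (length(missing_models) > 0) {
    stop("apply_calibration: no model for category: ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  cal <- vapply(seq_len(nrow(predictions)), function(i) {
    predict(models[[model_cat[i]]], predictions$e_prime_m_v[i])
  }, numeric(1))
  if (!is.null(activation_offset)) {
    act <- predictions$category == "G1-activated"
    cal[act] <- activation_correction(cal[act], activation_offset)
  }
  dplyr::mutate(tibble::as_tibble(predictions),
                calibrated_v = cal, method = "qc_calibrated")
}

#' Published per-category reference summary
#'
#' Compact reference table of the oxidoreductase categories: the number of
#' experimentally characterized reactions per category in the curated
#' 105-reaction compilation, the number of enumerated candidate reactions
#' among KEGG compounds with fewer than 7 carbons (652 in total), and the
#' reported category-mean transformed potentials (nearest 5 mV). Used for
#' carrier-analysis defaults and internal consistency checks; it is a
#' summary table, not raw data.
#'
#' @return A tibble with columns `category`, `n_experimental`,
#'   `n_enumerated`, `mean_e_prime_m_mv`.
#' @examples
#' category_reference()
#' sum(category_reference()$n_experimental)  # 105
#' @export
category_reference <- function() {
  tibble::tribble(
    ~category,      ~n_experimental, ~n_enumerated, ~mean_e_prime_m_mv,
    "G1",                        8L,           83L,               -550,
    "G1-activated",              NA_integer_,  NA_integer_,       -300,
    "G2",                       59L,          205L,               -225,
    "G3",                       23L,          104L,               -225,
    "G4",                       15L,          260L,                -15
  )
}

#' Redox reactions of the extended central metabolic network
#'
#' Static summary of the ~60 redox reactions shared by almost all
#' organisms' extended central metabolism (TCA cycle in either direction,
#' glycolysis/gluconeogenesis, pentose phosphate cycle, amino-acid,
#' nucleobase and fatty-acid biosynthesis), grouped by oxidoreductase
#' category and physiological direction, with the exceptional
#' hydrocarbon-oxidation reactions that exceed the NAD(P) range listed by
#' name. A reference lookup, not raw data: the full curated reaction list
#' is a supplementary artifact of the original compilation.
#'
#' @return A tibble with columns `group`, `direction`, `n_reactions`,
#'   `note`, `examples`.
#' @examples
#' sum(central_metabolism_reference()$n_reactions)  # ~60
#' @export
central_metabolism_reference <- function() {
  path <- system.file("extdata", "central_metabolism_redox_summary.csv",
                      package = "qcredox", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccicc", progress = FALSE)
}
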