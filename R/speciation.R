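#' Protonation-species ladder of a compound
#'
#' Builds the deprotonation ladder of a compound from its pH-0 major species
#' and its pKa list. Species 1 is the major species itself (Delta G0 = 0,
#' charge `z_ms`, hydrogen count `n_h_ms`); species j+1 removes the j-th
#' proton, with cumulative standard energy
#' \deqn{\Delta G^0_j = \sum_{i \le j} RT \ln(10)\, pK_{a,i}}
#' and z, n_h each reduced by one per step. Only pKa values inside
#' `pka_range` (default `[0, 14]`) generate species: values outside the
#' aqueous window cannot materially affect pH-7 pseudoisomer sums. Only
#' deprotonations from the pH-0 major species (the most protonated relevant
#' form) are modeled.
#'
#' @param pka numeric vector of pKa values in the order protons are removed
#'   from the major species (may be empty).
#' @param z_ms integer charge of the major species at pH 0.
#' @param n_h_ms integer hydrogen count of the major species at pH 0.
#' @param temperature temperature, K.
#' @param pka_range length-2 numeric; pKa values outside it are ignored.
#' @param constants a [redox_constants()] bundle.
#' @return A tibble with one row per species and columns `species` (1-based
#'   index), `dg0` (kJ/mol), `z`, `n_h`.
#' @examples
#' species_ladder(numeric(), z_ms = 0, n_h_ms = 4)      # single species
#' species_ladder(4.0, z_ms = 0, n_h_ms = 4)            # dg0 = 22.83 kJ/mol
#' species_ladder(c(3, 10), z_ms = -1, n_h_ms = 5)      # 17.12, 74.21 kJ/mol
#' @export
species_ladder <- function(pka, z_ms, n_h_ms, temperature = 298.15,
                           pka_range = c(0, 14),
                           constants = redox_constants()) {
  if (length(pka) > 0 && any(!is.finite(pka))) {
    stop("species_ladder: all pKa values must be finite", call. = FALSE)
  }
  pka_used <- pka[pka >= pka_range[1] & pka <= pka_range[2]]
  if (length(pka_used) > n_h_ms) {
    stop("species_ladder: pKa list implies removing ", length(pka_used),
         " protons but the major species has only ", n_h_ms, call. = FALSE)
  }
  rt <- rt_kj(temperature, constants)
  j <- seq_len(length(pka_used))
  tibble::tibble(
    species = c(1L, j + 1L),
    dg0 = c(0, cumsum(rt * log(10) * pka_used)),
    z = z_ms - c(0L, j),
    n_h = n_h_ms - c(0L, j)
  )
}

#' Species ladders for a compound table
#'
#' Data-frame interface over [species_ladder()]: takes a compound table (see
#' [read_compound_table()]) and returns one ladder row per species per
#' compound, keyed by `compound_id`.
#'
#' @param compounds a data frame with columns `id`, `charge`, `n_hydrogens`
#'   and `pka` (a list-column of numeric vectors, or a semicolon-separated
#'   character column).
#' @param temperature temperature, K.
#' @param pka_range pKa window passed to [species_ladder()].
#' @param constants a [redox_constants()] bundle.
#' @return A tibble with columns `compound_id`, `species`, `dg0`, `z`, `n_h`.
#' @export
build_species_ladders <- function(compounds, temperature = 298.15,
                                  pka_range = c(0, 14),
                                  constants = redox_constants()) {
  stopifnot(is.data.frame(compounds),
            all(c("id", "charge", "n_hydrogens") %in% names(compounds)))
  pka_list <- compound_pka_list(compounds)
  purrr::pmap_dfr(
    list(compounds$id, pka_list, compounds$charge, compounds$n_hydrogens),
    function(id, pka, z, nh) {
      ladder <- species_ladder(pka, z, nh, temperature, pka_range, constants)
      dplyr::bind_cols(tibble::tibble(compound_id = rep(id, nrow(ladder))),
                       ladder)
    }
  )
}

# Normalize the pKa column: list-column of numerics, or "a;b;c" strings.
compound_pka_list <- function(compounds) {
  if (!"pka" %in% names(compounds)) {
    return(rep(list(numeric()), nrow(compounds)))
  }
  pka <- compounds$pka
  if (is.list(pka)) {
    lapply(pka, function(p) as.numeric(p[!is.na(p)]))
  } else {
    lapply(as.character(pka), parse_pka_string)
  }
}

parse_pka_string <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(numeric())
  as.numeric(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
}

#' Dominant protonation species at given conditions
#'
#' Diagnostic helper: the ladder row whose Legendre-transformed energy is
#' minimal at the given pH and ionic strength. Ties break toward the more
#' protonated species (the lower index).
#'
#' @param ladder a species ladder from [species_ladder()].
#' @param conditions an [aqueous_conditions()] object.
#' @param constants a [redox_constants()] bundle.
#' @return Integer row index (1 = the pH-0 major species).
#' @examples
#' l <- species_ladder(4.0, z_ms = 0, n_h_ms = 4)
#' major_species_at_ph(l, aqueous_conditions(ph = 7, ionic_strength = 0)) # 2
#' @export
major_species_at_ph <- function(ladder, conditions = aqueous_conditions(),
                                constants = redox_constants()) {
  check_ladder(ladder, "ladder")
  gp <- legendre_transform(ladder$dg0, ladder$z, ladder$n_h,
                           conditions, constants)
  # first index within a hair of the minimum: ties (e.g. pKa exactly equal to
  # the pH) resolve toward the more protonated species
  which(gp <= min(gp) + 1e-9)[1]
}
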