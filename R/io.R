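#' Read and write compound tables
#'
#' CSV compound tables with one row per compound: `id`, `name`, `smiles`
#' (major protonation species at pH 0), `charge` and `n_hydrogens` (of that
#' species), `n_carbons`, `pka` (semicolon-separated, in deprotonation
#' order, may be empty) and `group_vector` (JSON object of named integer
#' functional-group counts). Rows failing validation are collected into the
#' `"problems"` attribute with their line numbers, not silently dropped;
#' missing required columns are an error naming the column.
#'
#' @param path file path.
#' @param x a compound tibble (for the writer).
#' @return `read_compound_table()`: a tibble (with a `pka` list-column
#'   added alongside the raw `pka` string). `write_compound_table()`: the
#'   input, invisibly. The two round-trip.
#' @export
read_compound_table <- function(path) {
  required <- c("id", "name", "smiles", "charge", "n_hydrogens",
                "n_carbons", "pka", "group_vector")
  # readr's name-mismatch warning is redundant with check_columns() below
  d <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), name = readr::col_character(),
    smiles = readr::col_character(), charge = readr::col_integer(),
    n_hydrogens = readr::col_integer(), n_carbons = readr::col_integer(),
    pka = readr::col_character(), group_vector = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE))
  check_columns(d, required, "read_compound_table")
  # empty cells in the optional text columns mean "none", not missing data
  d$pka[is.na(d$pka)] <- ""
  d$group_vector[is.na(d$group_vector)] <- ""
  problems <- validate_compounds(d)
  d$pka_list <- lapply(ifelse(is.na(d$pka), "", d$pka), parse_pka_string)
  ok <- !(seq_len(nrow(d)) %in% problems$line)
  out <- d[ok, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

validate_compounds <- function(d) {
  problems <- tibble::tibble(line = integer(), issue = character())
  flag <- function(i, msg) {
    problems <<- dplyr::bind_rows(problems,
                                  tibble::tibble(line = i, issue = msg))
  }
  for (i in seq_len(nrow(d))) {
    if (is.na(d$id[i]) || !nzchar(d$id[i])) flag(i, "missing id")
    if (is.na(d$smiles[i]) || !nzchar(d$smiles[i])) flag(i, "missing SMILES")
    if (!is.na(d$n_carbons[i]) && d$n_carbons[i] < 0) {
      flag(i, "negative carbon count")
    }
    if (!is.na(d$group_vector[i]) && nzchar(d$group_vector[i])) {
      gv <- tryCatch(parse_group_vector(d$group_vector[i]),
                     error = function(e) NULL)
      if (is.null(gv)) {
        flag(i, "unparseable group_vector JSON")
      } else if (any(gv < 0)) {
        flag(i, "negative functional-group count")
      }
    }
  }
  problems
}

#' @rdname read_compound_table
#' @export
write_compound_table <- function(x, path) {
  cols <- c("id", "name", "smiles", "charge", "n_hydrogens", "n_carbons",
            "pka", "group_vector")
  check_columns(x, cols, "write_compound_table")
  readr::write_csv(x[cols], path, na = "", progress = FALSE)
  invisible(x)
}

#' Read and write conformer-energy tables
#'
#' CSV tables with one row per conformer: `compound_id`, `conformer_index`,
#' `model_chemistry`, `energy_hartree`. Non-numeric energies are an error
#' reporting the offending line(s); a compound with more than 10 conformers
#' under one model chemistry draws a warning (conventional ensembles hold up
#' to 10), not an error. Energies are serialized at 17 significant digits so
#' read/write round-trips exactly.
#'
#' @param path file path.
#' @param x an energy tibble (for the writer).
#' @return `read_energy_table()`: a tibble. `write_energy_table()`: the
#'   input, invisibly.
#' @export
read_energy_table <- function(path) {
  required <- c("compound_id", "conformer_index", "model_chemistry",
                "energy_hartree")
  d <- readr::read_csv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    conformer_index = readr::col_integer(),
    model_chemistry = readr::col_character(),
    energy_hartree = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  check_columns(d, required, "read_energy_table")
  e <- suppressWarnings(as.numeric(d$energy_hartree))
  bad <- which(is.na(e) & !is.na(d$energy_hartree))
  if (length(bad) > 0) {
    stop("read_energy_table: non-numeric energy at data line(s) ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  d$energy_hartree <- e
  counts <- dplyr::count(d, .data$compound_id, .data$model_chemistry)
  over <- counts[counts$n > 10, ]
  if (nrow(over) > 0) {
    warning("read_energy_table: compound(s) with more than 10 conformers: ",
            paste(unique(over$compound_id), collapse = ", "), call. = FALSE)
  }
  d
}

#' @rdname read_energy_table
#' @export
write_energy_table <- function(x, path) {
  cols <- c("compound_id", "conformer_index", "model_chemistry",
            "energy_hartree")
  check_columns(x, cols, "write_energy_table")
  out <- x[cols]
  out$energy_hartree <- formatC(out$energy_hartree, format = "g", digits = 17)
  readr::write_csv(out, path, progress = FALSE)
  invisible(x)
}

#' Read and write experimental-potential tables
#'
#' CSV tables of experimental transformed potentials: `pair_id`, `category`
#' (one of [redox_categories()]), `e_prime_m_exp_v` (V), `source`, and
#' optionally prediction columns (`raw_qc_v`, `raw_fingerprint_v`, ...),
#' which are preserved as numeric. One value per reaction is ingested;
#' aggregation of replicate measurements is left to upstream curation.
#'
#' @param path file path.
#' @param x an experimental tibble (for the writer).
#' @return A tibble / the input invisibly.
#' @export
read_experimental_table <- function(path) {
  required <- c("pair_id", "category", "e_prime_m_exp_v")
  d <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  check_columns(d, required, "read_experimental_table")
  bad_cat <- setdiff(unique(d$category), redox_categories())
  if (length(bad_cat) > 0) {
    stop("read_experimental_table: unknown category label(s): ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(d$e_prime_m_exp_v))) {
    stop("read_experimental_table: non-finite experimental potential(s)",
         call. = FALSE)
  }
  d
}

#' @rdname read_experimental_table
#' @export
write_experimental_table <- function(x, path) {
  check_columns(x, c("pair_id", "category", "e_prime_m_exp_v"),
                "write_experimental_table")
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a subgroup-label table
#'
#' CSV with columns `pair_id` and one or more label columns (e.g.
#' `carbonyl_type`, `neighbor_group`, `sugar_ring`, `natural`, `cofactor`),
#' one row per pair, for [subgroup_comparison()].
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_label_table <- function(path) {
  d <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  check_columns(d, "pair_id", "read_label_table")
  if (anyDuplicated(d$pair_id)) {
    stop("read_label_table: duplicated pair_id rows", call. = FALSE)
  }
  d
}

#' Serialize calibration models as plain-text key-value records
#'
#' One block per category with `category`, `slope`, `intercept_v`, `n`,
#' `mae_v`, `pearson_r`, `r_squared` keys; numbers at full precision.
#' `read_calibration()` restores a named list of models usable by
#' [apply_calibration()] (the underlying `lm` object is not persisted; the
#' restored model predicts identically).
#'
#' @param models a named list of [fit_calibration()] models.
#' @param path file path.
#' @return `write_calibration()`: `models` invisibly; `read_calibration()`:
#'   a named list of `redox_calibration` objects.
#' @export
write_calibration <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    d <- m$diagnostics
    c(sprintf("category: %s", m$category),
      sprintf("slope: %.17g", m$slope),
      sprintf("intercept_v: %.17g", m$intercept),
      sprintf("n: %d", m$n),
      sprintf("mae_v: %.17g", d$mae),
      sprintf("pearson_r: %.17g", d$pearson_r),
      sprintf("r_squared: %.17g", d$r_squared),
      "")
  }))
  writeLines(lines, path)
  invisible(models)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  blocks <- split(lines, cumsum(!nzchar(lines)))
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0]
  models <- lapply(blocks, function(b) {
    kv <- strsplit(b, ": ", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- vapply(kv, `[`, character(1), 2)
    val <- function(k) vals[match(k, keys)]
    structure(
      list(category = val("category"),
           slope = as.numeric(val("slope")),
           intercept = as.numeric(val("intercept_v")),
           n = as.integer(val("n")),
           fit = NULL,
           diagnostics = tibble::tibble(
             mae = as.numeric(val("mae_v")),
             pearson_r = as.numeric(val("pearson_r")),
             r_squared = as.numeric(val("r_squared"))
           )),
      class = "redox_calibration"
    )
  })
  stats::setNames(models,
                  vapply(models, function(m) m$category, character(1)))
}

check_columns <- function(d, required, fn) {
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) {
    stop(fn, ": missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(d)
}
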