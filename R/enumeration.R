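#' Functional-group difference signatures of the oxidoreductase categories
#'
#' Each category is defined by the net change in functional-group counts from
#' the oxidized substrate to the reduced product (product minus substrate),
#' over a minimal named group basis sufficient to distinguish the four
#' transformations:
#' * G1: carboxylic acid -> carbonyl (`carbonyl +1, carboxylic_acid -1`)
#' * G2: carbonyl -> hydroxycarbon (`hydroxycarbon +1, carbonyl -1`)
#' * G3: carbonyl -> amine (`amine +1, carbonyl -1`; consumes one ammonia)
#' * G4: hydroxycarbon -> hydrocarbon (`hydrocarbon +1, hydroxycarbon -1`)
#'
#' The four signatures are mutually distinct, so an emitted pair maps to
#' exactly one category. Group vectors themselves are inputs carried on the
#' compound table; no structure-decomposition engine is involved.
#'
#' @return A tibble with columns `category`, `group`, `delta`, plus the
#'   attached co-reactant conventions (see [category_co_reactants()]).
#' @examples
#' category_signatures()
#' @export
category_signatures <- function() {
  tibble::tribble(
    ~category, ~group,            ~delta,
    "G1",      "carbonyl",         1L,
    "G1",      "carboxylic_acid", -1L,
    "G2",      "hydroxycarbon",    1L,
    "G2",      "carbonyl",        -1L,
    "G3",      "amine",            1L,
    "G3",      "carbonyl",        -1L,
    "G4",      "hydrocarbon",      1L,
    "G4",      "hydroxycarbon",   -1L
  )
}

# group_vector list-column -> matrix over the union basis
group_matrix <- function(compounds) {
  gv <- compounds$group_vector
  if (is.character(gv)) gv <- lapply(gv, parse_group_vector)
  basis <- sort(unique(unlist(lapply(gv, names))))
  m <- matrix(0L, nrow = length(gv), ncol = length(basis),
              dimnames = list(compounds$id, basis))
  for (i in seq_along(gv)) {
    v <- gv[[i]]
    if (length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v)))) {
        stop("match_pairs: group vector of compound '", compounds$id[i],
             "' has unnamed entries (inconsistent basis)", call. = FALSE)
      }
      m[i, names(v)] <- as.integer(v)
    }
  }
  if (any(m < 0)) {
    stop("match_pairs: negative functional-group counts found", call. = FALSE)
  }
  m
}

parse_group_vector <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(stats::setNames(integer(), character()))
  v <- jsonlite::fromJSON(s)
  stats::setNames(as.integer(unlist(v)), names(v))
}

#' Enumerate candidate redox pairs by group-difference matching
#'
#' All ordered compound pairs (substrate = oxidized, product = reduced) whose
#' functional-group difference vector (product minus substrate) equals the
#' category signature, restricted to compounds with fewer than `max_carbons`
#' carbon atoms. Output is deterministic: sorted by (substrate_id,
#' product_id).
#'
#' @param compounds a compound table with columns `id`, `n_carbons` and
#'   `group_vector` (named integer list-column or JSON strings over a shared
#'   group basis).
#' @param category one of "G1", "G2", "G3", "G4" (for [match_pairs()]), or a
#'   vector of categories (for [enumerate_redox_pairs()], default all four).
#' @param max_carbons pairs use only compounds with `n_carbons < max_carbons`
#'   (default 7).
#' @return A tibble with columns `pair_id`, `substrate_id`, `product_id`,
#'   `category`, `n_electrons`.
#' @export
match_pairs <- function(compounds, category, max_carbons = 7) {
  stopifnot(is.data.frame(compounds),
            all(c("id", "n_carbons", "group_vector") %in% names(compounds)))
  category <- match.arg(category, c("G1", "G2", "G3", "G4"))
  keep <- compounds$n_carbons < max_carbons
  comp <- compounds[keep, , drop = FALSE]
  empty <- tibble::tibble(pair_id = character(), substrate_id = character(),
                          product_id = character(), category = character(),
                          n_electrons = integer())
  if (nrow(comp) < 2) return(empty)

  gm <- group_matrix(comp)
  sig <- category_signatures()
  sig <- sig[sig$category == category, ]
  if (!all(sig$group %in% colnames(gm))) {
    # no compound carries the signature groups: nothing can match
    return(empty)
  }
  target <- stats::setNames(rep(0L, ncol(gm)), colnames(gm))
  target[sig$group] <- sig$delta

  n <- nrow(comp)
  idx <- expand.grid(s = seq_len(n), p = seq_len(n))
  idx <- idx[idx$s != idx$p, ]
  diffs <- gm[idx$p, , drop = FALSE] - gm[idx$s, , drop = FALSE]
  hit <- rowSums(diffs != rep(target, each = nrow(diffs))) == 0
  idx <- idx[hit, , drop = FALSE]
  out <- tibble::tibble(
    substrate_id = comp$id[idx$s],
    product_id = comp$id[idx$p],
    category = category,
    n_electrons = 2L
  )
  out <- out[order(out$substrate_id, out$product_id), ]
  out$pair_id <- paste(out$substrate_id, out$product_id, sep = "__")
  dplyr::relocate(out, "pair_id")
}

#' @rdname match_pairs
#' @export
enumerate_redox_pairs <- function(compounds,
                                  category = c("G1", "G2", "G3", "G4"),
                                  max_carbons = 7) {
  dplyr::bind_rows(lapply(category, function(g) {
    match_pairs(compounds, g, max_carbons)
  }))
}

#' Stereodescriptor tokens from a compound name
#'
#' Extracts R/S and L/D stereodescriptors from conventional compound-name
#' prefixes such as `(R)-`, `(S)-`, `L-`, `D-` (also inside composite
#' prefixes like `(2R,3S)-`). Used to drop enumerated pairs whose substrate
#' and product names disagree in chirality.
#'
#' @param name character vector of compound names.
#' @return A list of character vectors of tokens (possibly empty), uppercase.
#' @examples
#' stereo_tokens(c("(R)-lactate", "L-alanine", "pyruvate"))
#' @export
stereo_tokens <- function(name) {
  lapply(name, function(nm) {
    if (is.na(nm)) return(character())
    tokens <- character()
    # (R)-, (S)-, (2R,3S)- style prefixes anywhere in the name
    paren <- regmatches(nm, gregexpr("\\(([0-9]*[RS])(,[0-9]*[RS])*\\)-", nm))[[1]]
    if (length(paren)) {
      tokens <- c(tokens, unlist(regmatches(paren, gregexpr("[RS]", paren))))
    }
    # L-/D- prefixes at the start or after a space/hyphen
    ld <- regmatches(nm, gregexpr("(^|[ -])([LD])-", nm))[[1]]
    if (length(ld)) {
      tokens <- c(tokens, gsub("[^LD]", "", ld))
    }
    unique(toupper(tokens))
  })
}

#' Drop pairs whose names conflict in chirality
#'
#' A pair is retained unless both compound names carry stereodescriptor
#' tokens and the token sets differ (e.g. (R)- vs (S)-, or L- vs D-). Pairs
#' where either side has no tokens always pass; name conventions cannot
#' catch every stereochemical error (see [sugar_name_filter()] for the sugar
#' cases this rule lets through).
#'
#' @param pairs a pair table (from [match_pairs()]).
#' @param compounds a compound table with columns `id`, `name`.
#' @return The retained rows of `pairs`.
#' @export
chirality_filter <- function(pairs, compounds) {
  stopifnot(all(c("substrate_id", "product_id") %in% names(pairs)),
            all(c("id", "name") %in% names(compounds)))
  if (nrow(pairs) == 0) return(tibble::as_tibble(pairs))
  toks <- stereo_tokens(compounds$name)
  names(toks) <- compounds$id
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- toks[[pairs$substrate_id[i]]]
    b <- toks[[pairs$product_id[i]]]
    length(a) == 0 || length(b) == 0 || setequal(a, b)
  }, logical(1))
  tibble::as_tibble(pairs[keep, , drop = FALSE])
}

#' Default sugar-name correspondence rules
#'
#' Name roots of sugar families. Within an enumerated pair, if both compound
#' names contain a sugar root and the roots differ, the pair crosses sugar
#' families — a stereochemistry error that chirality tokens alone do not
#' catch (the classic false positive is L-xylonate -> L-arabinose, which
#' passes the L/L token match). The table is user-extensible.
#'
#' @return A tibble with column `root` (lowercase name fragments).
#' @export
default_sugar_rules <- function() {
  tibble::tibble(root = c("glucos", "galactos", "mannos", "fructos",
                          "arabino", "xylo", "ribo", "lyxo", "erythro",
                          "threo", "gulono", "idono", "allos", "altros",
                          "sorbos", "tagatos", "fucos", "rhamnos"))
}

#' Remove cross-family sugar pairs by name convention
#'
#' Applies a sugar name-root correspondence table (see
#' [default_sugar_rules()]): pairs whose substrate and product names match
#' *different* sugar roots are removed. Pairs matching no root, one root, or
#' the same root on both sides are retained. Rule hits are recorded in the
#' `"rule_log"` attribute of the result.
#'
#' @param pairs a pair table.
#' @param compounds a compound table with columns `id`, `name`.
#' @param rules a rules table with a `root` column; an empty table makes the
#'   filter the identity.
#' @return The retained rows of `pairs`, with attribute `rule_log` (a tibble
#'   of removed pairs and the roots that fired).
#' @export
sugar_name_filter <- function(pairs, compounds, rules = default_sugar_rules()) {
  stopifnot(all(c("substrate_id", "product_id") %in% names(pairs)),
            all(c("id", "name") %in% names(compounds)))
  out <- tibble::as_tibble(pairs)
  log <- tibble::tibble(pair_id = character(), substrate_root = character(),
                        product_root = character())
  if (nrow(out) == 0 || nrow(rules) == 0) {
    attr(out, "rule_log") <- log
    return(out)
  }
  name_of <- stats::setNames(tolower(compounds$name), compounds$id)
  root_of <- function(nm) {
    hits <- rules$root[vapply(rules$root, grepl, logical(1), x = nm,
                              fixed = TRUE)]
    if (length(hits) == 0) NA_character_ else hits[[1]]
  }
  s_root <- vapply(name_of[out$substrate_id], root_of, character(1))
  p_root <- vapply(name_of[out$product_id], root_of, character(1))
  drop <- !is.na(s_root) & !is.na(p_root) & s_root != p_root
  if (any(drop)) {
    log <- tibble::tibble(
      pair_id = out$pair_id[drop],
      substrate_root = unname(s_root[drop]),
      product_root = unname(p_root[drop])
    )
  }
  res <- out[!drop, , drop = FALSE]
  attr(res, "rule_log") <- log
  res
}

#' Independently re-verify emitted pairs against their category signature
#'
#' Post-hoc checker: recomputes each pair's group-difference vector directly
#' from the compound table and compares it with the category signature,
#' without going through the matcher's internals.
#'
#' @param pairs a pair table with `substrate_id`, `product_id`, `category`.
#' @param compounds the compound table the pairs were enumerated from.
#' @return `TRUE` invisibly if every pair checks out; otherwise an error
#'   naming the offending pair(s).
#' @export
verify_pairs <- function(pairs, compounds) {
  if (nrow(pairs) == 0) return(invisible(TRUE))
  gm <- group_matrix(compounds)
  sig_tbl <- category_signatures()
  bad <- character()
  for (i in seq_len(nrow(pairs))) {
    sig <- sig_tbl[sig_tbl$category == pairs$category[i], ]
    d <- gm[pairs$product_id[i], ] - gm[pairs$substrate_id[i], ]
    expected <- stats::setNames(rep(0L, ncol(gm)), colnames(gm))
    expected[sig$group] <- sig$delta
    if (!identical(unname(d[colnames(gm)]), unname(expected)) &&
        !all(d == expected)) {
      bad <- c(bad, pairs$pair_id[i])
    }
  }
  if (length(bad)) {
    stop("verify_pairs: signature violated for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
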