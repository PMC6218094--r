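#' MACCS 166-key fingerprints for compounds
#'
#' Evaluates the public 166-key MACCS substructure dictionary on each SMILES
#' (via OpenBabel's MACCS SMARTS definitions, through ChemmineOB). Key k of
#' the dictionary is column k of the result. Fingerprints are computed on the
#' pH-0 major-species SMILES, the structure the compound table carries.
#'
#' MACCS keys were chosen over richer circular fingerprints deliberately: a
#' short fixed dictionary keeps the regression design small relative to the
#' available training sets.
#'
#' @param smiles character vector of SMILES strings; unparseable entries
#'   raise an error naming the offending string.
#' @return An integer 0/1 matrix, `length(smiles)` x 166, with the SMILES as
#'   row names (where unique) and columns `key1` ... `key166`.
#' @examples
#' \donttest{
#' maccs_keys("CCO")["CCO", c("key82", "key160")]
#' }
#' @export
maccs_keys <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  rows <- lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      stop("maccs_keys: empty or missing SMILES string", call. = FALSE)
    }
    mol <- tryCatch(
      ChemmineOB::forEachMol("SMILES", s, identity),
      error = function(e) {
        stop("maccs_keys: could not parse SMILES '", s, "'", call. = FALSE)
      }
    )
    bits <- ChemmineOB::fingerprint_OB(mol, "MACCS")
    as.integer(bits[seq_len(166)])   # OpenBabel pads the bit vector
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("key", seq_len(166))
  if (!anyDuplicated(smiles)) rownames(m) <- smiles
  m
}

#' Concatenated reaction fingerprints for redox pairs
#'
#' One half-reaction is encoded as the 332-bit concatenation of its substrate
#' (oxidized) and product (reduced) MACCS keys: substrate keys occupy columns
#' 1-166 (`s_key*`), product keys columns 167-332 (`p_key*`).
#'
#' @param pairs a data frame with columns `pair_id`, `substrate_id`,
#'   `product_id`.
#' @param compounds a compound table with columns `id` and `smiles`.
#' @return An integer 0/1 matrix, `nrow(pairs)` x 332, row names `pair_id`.
#' @export
reaction_fingerprints <- function(pairs, compounds) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "substrate_id", "product_id") %in% names(pairs)),
            is.data.frame(compounds),
            all(c("id", "smiles") %in% names(compounds)))
  ids_needed <- unique(c(pairs$substrate_id, pairs$product_id))
  missing_ids <- setdiff(ids_needed, compounds$id)
  if (length(missing_ids) > 0) {
    stop("reaction_fingerprints: no structure for compound(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  comp <- compounds[match(ids_needed, compounds$id), ]
  keys <- maccs_keys(comp$smiles)
  rownames(keys) <- ids_needed
  concat_fingerprints(keys[pairs$substrate_id, , drop = FALSE],
                      keys[pairs$product_id, , drop = FALSE],
                      pairs$pair_id)
}

#' Concatenate substrate and product key blocks
#'
#' Low-level assembly of a reaction fingerprint from two 166-column key
#' matrices (or single 166-vectors); exposed so the bit layout is testable
#' in isolation.
#'
#' @param substrate_keys,product_keys 0/1 matrices with 166 columns (or
#'   length-166 vectors).
#' @param pair_id optional row names for the result.
#' @return An integer 0/1 matrix with 332 columns.
#' @export
concat_fingerprints <- function(substrate_keys, product_keys, pair_id = NULL) {
  if (is.null(dim(substrate_keys))) substrate_keys <- rbind(substrate_keys)
  if (is.null(dim(product_keys))) product_keys <- rbind(product_keys)
  if (ncol(substrate_keys) != 166 || ncol(product_keys) != 166) {
    stop("concat_fingerprints: key blocks must have exactly 166 columns",
         call. = FALSE)
  }
  if (nrow(substrate_keys) != nrow(product_keys)) {
    stop("concat_fingerprints: substrate and product blocks differ in rows",
         call. = FALSE)
  }
  m <- cbind(substrate_keys, product_keys)
  colnames(m) <- c(paste0("s_key", seq_len(166)), paste0("p_key", seq_len(166)))
  rownames(m) <- pair_id
  storage.mode(m) <- "integer"
  m
}

#' Lasso regression of potentials on reaction fingerprints
#'
#' L1-regularized least squares of experimental potentials on 0/1 reaction
#' fingerprint bits, one model per oxidoreductase category. When `lambda` is
#' `NULL` it is chosen by k-fold cross-validation with a fold assignment
#' derived deterministically from `seed` (lambda.min); the model is then
#' refit on all rows at that lambda. Given `seed` and `lambda` the fit is
#' fully deterministic and invariant to training-row order.
#'
#' @param fingerprints 0/1 matrix (rows = reactions, columns = bits), e.g.
#'   from [reaction_fingerprints()].
#' @param values numeric vector of experimental potentials (V), one per row.
#' @param lambda regularization strength; `NULL` (default) for seeded
#'   cross-validated selection. Must be >= 0. `lambda = 0` gives ordinary
#'   least squares.
#' @param seed integer seed controlling the cross-validation folds.
#' @param nfolds folds for cross-validation (default 5; capped at the number
#'   of rows).
#' @return An object of class `redox_fingerprint_model`: list with `fit`
#'   (glmnet), `lambda`, `lambda_grid`, `nfolds`, `seed`, `n`,
#'   `diagnostics` (in-sample [evaluate_predictions()]).
#' @export
fit_fingerprint_model <- function(fingerprints, values, lambda = NULL,
                                  seed = 1, nfolds = 5) {
  x <- as.matrix(fingerprints)
  if (nrow(x) != length(values)) {
    stop("fit_fingerprint_model: rows of `fingerprints` and length of ",
         "`values` differ", call. = FALSE)
  }
  if (nrow(x) < 2) {
    stop("fit_fingerprint_model: need at least 2 training reactions",
         call. = FALSE)
  }
  if (!is.null(lambda) && lambda < 0) {
    stop("fit_fingerprint_model: `lambda` must be >= 0", call. = FALSE)
  }
  # order-invariant canonical row order for fold assignment and fitting
  ord <- order(rownames(x) %||% apply(x, 1, paste, collapse = ""), values)
  x <- x[ord, , drop = FALSE]
  y <- values[ord]
  lambda_grid <- NULL
  if (is.null(lambda)) {
    nfolds <- min(nfolds, nrow(x))
    foldid <- withr::with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                            standardize = FALSE)
    lambda <- cv$lambda.min
    lambda_grid <- cv$lambda
  }
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda,
                        standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  obj <- structure(
    list(fit = fit, lambda = lambda, lambda_grid = lambda_grid,
         nfolds = nfolds, seed = seed, n = nrow(x), diagnostics = NULL),
    class = "redox_fingerprint_model"
  )
  obj$diagnostics <- evaluate_predictions(predict(obj, x), y)
  obj
}

#' @export
print.redox_fingerprint_model <- function(x, ...) {
  nz <- sum(coef(x) != 0)
  cat(sprintf("<redox_fingerprint_model> n = %d, lambda = %.3g, %d nonzero weights\n",
              x$n, x$lambda, nz))
  d <- x$diagnostics
  cat(sprintf("  in-sample MAE %.1f mV, R^2 %.3f\n", 1000 * d$mae, d$r_squared))
  invisible(x)
}

#' @param object a `redox_fingerprint_model`.
#' @param newdata fingerprint matrix with the training columns.
#' @param ... unused.
#' @rdname fit_fingerprint_model
#' @export
predict.redox_fingerprint_model <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newx = as.matrix(newdata),
                            s = object$lambda))
}

#' @export
coef.redox_fingerprint_model <- function(object, ...) {
  cf <- as.matrix(stats::coef(object$fit, s = object$lambda))[, 1]
  cf[-1]   # drop intercept; weights named by bit
}

#' @rdname tidy.redox_calibration
#' @method glance redox_fingerprint_model
#' @export
glance.redox_fingerprint_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = x$n, lambda = x$lambda,
                   n_nonzero = sum(coef(x) != 0)),
    x$diagnostics
  )
}

#' @rdname tidy.redox_calibration
#' @method tidy redox_fingerprint_model
#' @export
tidy.redox_fingerprint_model <- function(x, ...) {
  cf <- coef(x)
  tibble::tibble(term = names(cf), estimate = unname(cf))[cf != 0, ]
}

intercept_of <- function(object) {
  as.matrix(stats::coef(object$fit, s = object$lambda))[1, 1]
}
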