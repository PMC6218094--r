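#' Two-parameter linear calibration of predicted potentials
#'
#' Ordinary least squares of experimental on raw predicted potentials within
#' one oxidoreductase category: calibrated = alpha * raw + beta. The raw
#' quantum predictions carry a category-specific systematic error (mostly
#' from omitted rovibrational thermochemistry); two parameters per category
#' absorb it. Activated-G1 records share the G1 model.
#'
#' @param data a data frame with columns `raw` and `experimental` (V),
#'   optionally `pair_id`; rows are paired observations of one category.
#' @param category optional category label stored in the model.
#' @return An object of class `redox_calibration`: list with `category`,
#'   `slope`, `intercept` (V), `n`, `fit` (the underlying `lm`) and
#'   `diagnostics` (tibble from [evaluate_predictions()], recomputed at fit
#'   time). Use [predict()][predict.redox_calibration()],
#'   [tidy()][tidy.redox_calibration()] and
#'   [glance()][glance.redox_calibration()].
#' @examples
#' d <- tibble::tibble(raw = c(-0.3, -0.2, -0.1), experimental = c(-0.25, -0.17, -0.09))
#' m <- fit_calibration(d, "G2")
#' predict(m, d)
#' @export
fit_calibration <- function(data, category = NULL) {
  stopifnot(is.data.frame(data),
            all(c("raw", "experimental") %in% names(data)))
  data <- data[stats::complete.cases(data[c("raw", "experimental")]), ,
               drop = FALSE]
  if (nrow(data) < 2) {
    stop("fit_calibration: need at least 2 paired observations",
         call. = FALSE)
  }
  if (stats::sd(data$raw) == 0) {
    stop("fit_calibration: raw predictions have zero variance; ",
         "slope is unidentifiable", call. = FALSE)
  }
  fit <- stats::lm(experimental ~ raw, data = data)
  calibrated <- unname(stats::fitted(fit))
  structure(
    list(
      category = category %||% NA_character_,
      slope = unname(stats::coef(fit)[["raw"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      n = nrow(data),
      fit = fit,
      diagnostics = evaluate_predictions(calibrated, data$experimental)
    ),
    class = "redox_calibration"
  )
}

#' Per-category calibration models
#'
#' Fits [fit_calibration()] independently for each category present in
#' `data`. Records labelled `"G1-activated"` are folded into the `"G1"` fit
#' (too few activated measurements exist for a separate model).
#'
#' @param data a data frame with columns `category`, `raw`, `experimental`.
#' @return A named list of `redox_calibration` objects.
#' @export
fit_calibration_by_category <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("category", "raw", "experimental") %in% names(data)))
  d <- data
  d$category[d$category == "G1-activated"] <- "G1"
  cats <- sort(unique(d$category))
  stats::setNames(
    lapply(cats, function(g) {
      fit_calibration(d[d$category == g, , drop = FALSE], category = g)
    }),
    cats
  )
}

#' @export
print.redox_calibration <- function(x, ...) {
  cat(sprintf("<redox_calibration> category %s: E_cal = %.4f * E_raw %+0.4f V (n = %d)\n",
              x$category, x$slope, x$intercept, x$n))
  d <- x$diagnostics
  cat(sprintf("  MAE %.1f mV, Pearson r %.3f, R^2 %.3f\n",
              1000 * d$mae, d$pearson_r, d$r_squared))
  invisible(x)
}

#' Apply a calibration model to new raw predictions
#'
#' @param object a `redox_calibration` model.
#' @param newdata a data frame with a `raw` column, or a numeric vector of
#'   raw potentials (V).
#' @param ... unused.
#' @return Calibrated potentials, V.
#' @export
predict.redox_calibration <- function(object, newdata, ...) {
  raw <- if (is.data.frame(newdata)) newdata$raw else newdata
  object$slope * raw + object$intercept
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style accessors for calibration models
#'
#' `tidy()` returns the slope/intercept terms; `glance()` returns one row of
#' fit diagnostics (n, MAE in V, Pearson r, R^2).
#'
#' @param x a `redox_calibration` model.
#' @param ... unused.
#' @return A tibble.
#' @method tidy redox_calibration
#' @export
tidy.redox_calibration <- function(x, ...) {
  tibble::tibble(
    category = x$category,
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @rdname tidy.redox_calibration
#' @method glance redox_calibration
#' @export
glance.redox_calibration <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(category = x$category, n = x$n),
                   x$diagnostics)
}

#' Prediction-quality metrics
#'
#' Mean absolute error, Pearson correlation and coefficient of determination
#' R^2 = 1 - SS_res/SS_tot. R^2 may be negative (worse than the constant
#' mean predictor, which scores exactly 0). A constant experimental vector
#' makes Pearson r undefined; it is reported as `NA`, not an error.
#'
#' @param pred,experimental equal-length numeric vectors (V), length >= 2.
#' @return A one-row tibble with columns `mae` (V), `pearson_r`, `r_squared`.
#' @examples
#' evaluate_predictions(c(0, 0, 0, 0), c(-1, 0, 1, 2))  # MAE 1, R^2 -0.2
#' @export
evaluate_predictions <- function(pred, experimental) {
  if (length(pred) != length(experimental)) {
    stop("evaluate_predictions: `pred` and `experimental` lengths differ",
         call. = FALSE)
  }
  if (length(pred) < 2) {
    stop("evaluate_predictions: need at least 2 observations", call. = FALSE)
  }
  ss_res <- sum((experimental - pred)^2)
  ss_tot <- sum((experimental - mean(experimental))^2)
  r <- if (stats::sd(experimental) == 0 || stats::sd(pred) == 0) {
    NA_real_
  } else {
    stats::cor(pred, experimental)
  }
  tibble::tibble(
    mae = mean(abs(pred - experimental)),
    pearson_r = r,
    r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  )
}

#' Z-scores of prediction errors
#'
#' Normalizes prediction errors to z-scores, (err - mean)/sd, using the
#' sample standard deviation (ddof = 1), so that error magnitudes from
#' different prediction methods become comparable.
#'
#' @param errors numeric vector of signed prediction errors (V); length >= 2
#'   with nonzero spread.
#' @return Numeric vector of z-scores.
#' @examples
#' error_zscores(c(0, 0, 0, 4))  # -0.5 -0.5 -0.5 1.5
#' @export
error_zscores <- function(errors) {
  if (length(errors) < 2) {
    stop("error_zscores: need at least 2 errors", call. = FALSE)
  }
  s <- stats::sd(errors)
  if (!is.finite(s) || s == 0) {
    stop("error_zscores: errors have zero spread", call. = FALSE)
  }
  (errors - mean(errors)) / s
}

#' Cross-method joint outlier detection
#'
#' Flags reactions whose prediction error is anomalous under two independent
#' prediction methods simultaneously: |z| > `threshold` for both. Consistent
#' deviation from two very different predictors points at the experimental
#' value rather than at either model.
#'
#' @param data a data frame with columns `pair_id`, `z_qc`, `z_fingerprint`
#'   (aligned rows).
#' @param threshold z-score threshold (default 2). The absolute value is
#'   used: both flagged literature examples deviate in one direction, but a
#'   symmetric rule is the safer reading.
#' @return The flagged rows of `data`, as a tibble.
#' @export
joint_outliers <- function(data, threshold = 2) {
  stopifnot(is.data.frame(data),
            all(c("pair_id", "z_qc", "z_fingerprint") %in% names(data)))
  if (anyNA(data$z_qc) || anyNA(data$z_fingerprint)) {
    stop("joint_outliers: z-scores contain missing values", call. = FALSE)
  }
  tibble::as_tibble(
    data[abs(data$z_qc) > threshold & abs(data$z_fingerprint) > threshold, ,
         drop = FALSE]
  )
}
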