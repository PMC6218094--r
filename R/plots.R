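#' Calibration scatter plot
#'
#' Experimental vs calibrated potentials for a fitted calibration model,
#' with the identity line; the standard visual check that the two-parameter
#' fit removed the systematic error.
#'
#' @param object a [fit_calibration()] model (must retain its `lm` fit).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot redox_calibration
#' @export
autoplot.redox_calibration <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("autoplot.redox_calibration: model was deserialized without its ",
         "training data; refit to plot", call. = FALSE)
  }
  d <- tibble::tibble(
    calibrated = unname(stats::fitted(object$fit)),
    experimental = object$fit$model$experimental
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$calibrated,
                                  y = .data$experimental)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "calibrated prediction E'm (V)",
      y = "experimental E'm (V)",
      title = sprintf("Category %s calibration (n = %d, MAE %.0f mV)",
                      object$category, object$n,
                      1000 * object$diagnostics$mae)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Distribution of predicted potentials by category
#'
#' Density curves of E'm per oxidoreductase category with the carrier's
#' physiological range (shaded) and its concentration-widened reversibility
#' window (dashed) overlaid — the at-a-glance view of which chemistry a
#' carrier can drive reversibly.
#'
#' @param estimates a data frame with `category` and the potential column.
#' @param carrier a [carrier_profile()] (set `NULL` to omit the overlay).
#' @param potential_col potential column name (default `"e_prime_m_v"`).
#' @return A ggplot object.
#' @export
plot_potential_distributions <- function(estimates,
                                         carrier = carrier_profile(),
                                         potential_col = "e_prime_m_v") {
  stopifnot(is.data.frame(estimates),
            all(c("category", potential_col) %in% names(estimates)))
  p <- ggplot2::ggplot(estimates,
                       ggplot2::aes(x = 1000 * .data[[potential_col]],
                                    fill = .data$category,
                                    colour = .data$category))
  if (!is.null(carrier)) {
    win <- reversibility_window(carrier$e_low, carrier$e_high,
                                carrier$concentration_span)
    p <- p +
      ggplot2::annotate("rect", xmin = 1000 * carrier$e_low,
                        xmax = 1000 * carrier$e_high,
                        ymin = -Inf, ymax = Inf, alpha = 0.15) +
      ggplot2::geom_vline(xintercept = 1000 * c(win$e_min, win$e_max),
                          linetype = "dashed", colour = "grey40")
  }
  p +
    ggplot2::geom_density(alpha = 0.3) +
    ggplot2::labs(x = "E'm (mV)", y = "density") +
    ggplot2::theme_minimal()
}

#' Cross-method z-score scatter for outlier triage
#'
#' Prediction-error z-scores of one method against the other, with the
#' joint-outlier threshold box; points outside the box in both coordinates
#' are the candidate erroneous experimental values.
#'
#' @param data a data frame with columns `pair_id`, `z_qc`, `z_fingerprint`.
#' @param threshold z threshold drawn and used for highlighting (default 2).
#' @return A ggplot object.
#' @export
plot_outlier_zscores <- function(data, threshold = 2) {
  stopifnot(all(c("pair_id", "z_qc", "z_fingerprint") %in% names(data)))
  flagged <- abs(data$z_qc) > threshold & abs(data$z_fingerprint) > threshold
  d <- dplyr::mutate(tibble::as_tibble(data), flagged = flagged)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_qc, y = .data$z_fingerprint,
                                  colour = .data$flagged)) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "z (quantum chemistry error)",
                  y = "z (fingerprint error)") +
    ggplot2::theme_minimal()
}
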