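#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test for a difference in means without assuming equal
#' variances, with the Welch-Satterthwaite degrees of freedom. Computed from
#' the closed-form statistics (and cross-checked in the test suite against
#' `stats::t.test`).
#'
#' @param a,b numeric vectors, each with >= 2 values and nonzero variance.
#' @return A one-row tibble with columns `t`, `df`, `p_value`,
#'   `delta_mean` (mean(a) - mean(b)).
#' @examples
#' welch_t_test(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_t_test: each group needs at least 2 values", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) {
    stop("welch_t_test: degenerate group (zero variance)", call. = FALSE)
  }
  se2 <- va / length(a) + vb / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  tibble::tibble(
    t = t_stat,
    df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    delta_mean = mean(a) - mean(b)
  )
}

#' Per-category summary of transformed potentials
#'
#' Mean, median and count of E'm per category, reported in mV, with a
#' display-rounded mean (nearest multiple of 5 mV, the reporting convention
#' for category averages). Rounding is applied only to the `rounded_mean_mv`
#' column, never to the underlying values.
#'
#' @param estimates a data frame with columns `category` and the potential
#'   column named by `potential_col` (in V).
#' @param potential_col name of the potential column (default
#'   `"e_prime_m_v"`).
#' @return A tibble with columns `category`, `n`, `mean_mv`, `median_mv`,
#'   `rounded_mean_mv`.
#' @export
category_summary <- function(estimates, potential_col = "e_prime_m_v") {
  stopifnot(is.data.frame(estimates),
            "category" %in% names(estimates),
            potential_col %in% names(estimates))
  if (nrow(estimates) == 0) {
    stop("category_summary: no estimates supplied", call. = FALSE)
  }
  estimates |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_mv = 1000 * mean(.data[[potential_col]]),
      median_mv = 1000 * stats::median(.data[[potential_col]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(rounded_mean_mv = round_to_nearest(.data$mean_mv, 5))
}

#' Physiological profile of an electron carrier
#'
#' An electron carrier is characterized by the range its potential spans in
#' vivo (set by its standard potential and the physiological range of its
#' reduced:oxidized ratio) and by the concentration span its redox partners
#' can explore. The default is NAD(P): standard potential ~ -330 mV at pH 7,
#' I 0.25 M, physiological range -380 to -250 mV, partner concentrations
#' spanning 10^4 (1 uM to 10 mM).
#'
#' @param name carrier name.
#' @param e_low,e_high physiological potential range, V.
#' @param concentration_span partner-metabolite concentration span; >= 1.
#' @param e_standard standard transformed potential, V (informational).
#' @return A list of class `carrier_profile`.
#' @examples
#' carrier_profile()
#' @export
carrier_profile <- function(name = "NAD(P)", e_low = -0.380, e_high = -0.250,
                            concentration_span = 1e4, e_standard = -0.330) {
  if (e_low > e_high) {
    stop("carrier_profile: `e_low` must be <= `e_high`", call. = FALSE)
  }
  if (concentration_span < 1) {
    stop("carrier_profile: `concentration_span` must be >= 1", call. = FALSE)
  }
  structure(list(name = name, e_low = e_low, e_high = e_high,
                 concentration_span = concentration_span,
                 e_standard = e_standard),
            class = "carrier_profile")
}

#' @export
print.carrier_profile <- function(x, ...) {
  cat(sprintf("<carrier_profile> %s: %.0f to %.0f mV, span %.3g\n",
              x$name, 1000 * x$e_low, 1000 * x$e_high, x$concentration_span))
  invisible(x)
}

#' Classify couples against a carrier's reversibility window
#'
#' Each couple potential is compared with the carrier's concentration-widened
#' window (see [reversibility_window()]). Inside the window (closed
#' interval) the carrier can drive the couple both ways (`reversible`).
#' Below the window the couple potential is too low for the carrier to
#' reduce it: only oxidation of the reduced compound is feasible
#' (`oxidation_only`, e.g. carbonyl-to-acid oxidations). Above the window
#' only reduction by the carrier's reduced form is feasible
#' (`reduction_only`, e.g. hydroxycarbon-to-hydrocarbon reductions). The
#' three labels partition the real line.
#'
#' @param estimates a data frame with the potential column named by
#'   `potential_col` (V), or a bare numeric vector.
#' @param carrier a [carrier_profile()].
#' @param potential_col potential column name (default `"e_prime_m_v"`).
#' @param n_electrons electrons transferred.
#' @param temperature temperature, K.
#' @param constants a [redox_constants()] bundle.
#' @return For a data frame input, the input with an added `carrier_class`
#'   column; for a vector, a character vector of labels.
#' @examples
#' classify_vs_carrier(c(-0.550, -0.300, -0.015))
#' @export
classify_vs_carrier <- function(estimates, carrier = carrier_profile(),
                                potential_col = "e_prime_m_v",
                                n_electrons = 2, temperature = 298.15,
                                constants = redox_constants()) {
  win <- reversibility_window(carrier$e_low, carrier$e_high,
                              carrier$concentration_span, n_electrons,
                              temperature, constants)
  label <- function(e) {
    dplyr::case_when(
      e < win$e_min ~ "oxidation_only",
      e > win$e_max ~ "reduction_only",
      TRUE ~ "reversible"
    )
  }
  if (is.data.frame(estimates)) {
    stopifnot(potential_col %in% names(estimates))
    dplyr::mutate(tibble::as_tibble(estimates),
                  carrier_class = label(.data[[potential_col]]))
  } else {
    label(estimates)
  }
}

#' Pairwise subgroup comparison of transformed potentials
#'
#' For every unordered pair of labels on one structural axis (e.g. aldehyde
#' vs ketone, open-chain vs ring-opening sugars, natural vs non-natural),
#' reports the difference of subgroup means (mV) and the Welch two-sided
#' p-value. No multiplicity correction is applied by default, matching the
#' convention of reporting raw Welch p-values per axis; set
#' `p_adjust = "BH"` for Benjamini-Hochberg-adjusted p-values.
#'
#' @param estimates a data frame with a `pair_id` column and the potential
#'   column named by `potential_col` (V).
#' @param labels a data frame with columns `pair_id` and the label column
#'   named by `axis`. Every estimate must be labeled; unlabeled ids are an
#'   error listing the offenders.
#' @param axis name of the label column in `labels`.
#' @param potential_col potential column name (default `"e_prime_m_v"`).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A tibble with columns `label_a`, `label_b`, `n_a`, `n_b`,
#'   `delta_mean_mv` (mean_a - mean_b), `t`, `df`, `p_value`.
#' @export
subgroup_comparison <- function(estimates, labels, axis,
                                potential_col = "e_prime_m_v",
                                p_adjust = "none") {
  stopifnot(is.data.frame(estimates), "pair_id" %in% names(estimates),
            potential_col %in% names(estimates),
            is.data.frame(labels), all(c("pair_id", axis) %in% names(labels)))
  unlabeled <- setdiff(estimates$pair_id, labels$pair_id)
  if (length(unlabeled) > 0) {
    stop("subgroup_comparison: unlabeled pair(s) on axis '", axis, "': ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  d <- dplyr::inner_join(estimates, labels[c("pair_id", axis)],
                         by = "pair_id")
  groups <- split(d[[potential_col]], d[[axis]])
  labs <- names(groups)
  if (length(labs) < 2) {
    stop("subgroup_comparison: need at least two subgroups on axis '",
         axis, "'", call. = FALSE)
  }
  combos <- utils::combn(labs, 2, simplify = FALSE)
  out <- purrr::map_dfr(combos, function(pr) {
    wt <- welch_t_test(groups[[pr[1]]], groups[[pr[2]]])
    tibble::tibble(
      label_a = pr[1], label_b = pr[2],
      n_a = length(groups[[pr[1]]]), n_b = length(groups[[pr[2]]]),
      delta_mean_mv = 1000 * wt$delta_mean,
      t = wt$t, df = wt$df, p_value = wt$p_value
    )
  })
  if (!identical(p_adjust, "none")) {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}
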