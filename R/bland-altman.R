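#' Bland-Altman series on the ratio scale
#'
#' Per-lesion data for a log-log Bland-Altman plot: `x` is the geometric mean
#' of the test and retest feature values, `y` the retest/test ratio, both
#' meant for log-scaled axes, with the back-transformed bias line `exp(d_bar)`
#' and LOA lines `exp(d_bar +/- 1.96 sigma)` attached.
#'
#' @inheritParams log_ratios
#' @param vc The [variance_components()] of the same stratum (lesion counts
#'   must agree).
#' @return A tibble of class `bland_altman` with columns `patient_id`,
#'   `lesion_id`, `x`, `y` and attributes `feature`, `bias_line`,
#'   `loa_lower_line`, `loa_upper_line`.
#' @export
bland_altman_series <- function(pairs, feature = FEATURES, vc) {
  feature <- match.arg(feature)
  check_pairs(pairs, feature)
  if (!inherits(vc, "variance_components")) {
    abort_structure("`vc` must be a `variance_components` object.")
  }
  if (vc$n_lesions != nrow(pairs)) {
    abort(sprintf(
      "`vc` was computed from %d lesions but `pairs` has %d; stratum mismatch.",
      vc$n_lesions, nrow(pairs)), class = "petrep_error_consistency")
  }
  x1 <- pairs[[paste0(feature, "_test")]]
  x2 <- pairs[[paste0(feature, "_retest")]]
  if (any(x1 <= 0 | x2 <= 0)) {
    abort_validation("feature values must be positive for a ratio plot.")
  }
  out <- tibble::tibble(
    patient_id = pairs$patient_id,
    lesion_id = pairs$lesion_id,
    x = sqrt(x1 * x2),
    y = x2 / x1
  )
  attr(out, "feature") <- feature
  attr(out, "bias_line") <- exp(vc$d_bar)
  attr(out, "loa_lower_line") <- exp(vc$d_bar - 1.96 * vc$sigma)
  attr(out, "loa_upper_line") <- exp(vc$d_bar + 1.96 * vc$sigma)
  class(out) <- c("bland_altman", class(out))
  out
}

#' @describeIn bland_altman_series Log-log Bland-Altman scatter with
#'   per-patient colors, solid bias line and dashed LOA lines.
#' @param object A `bland_altman` tibble.
#' @param ... Unused.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  feature <- attr(object, "feature")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$patient_id)) +
    ggplot2::geom_hline(yintercept = attr(object, "bias_line")) +
    ggplot2::geom_hline(yintercept = attr(object, "loa_lower_line"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "loa_upper_line"),
                        linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8, size = 1.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("geometric mean of test and retest %s", feature),
                  y = "retest / test ratio", colour = "patient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
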