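#' Per-lesion log-ratios of retest to test measurements
#'
#' SUV-based features are right-skewed, so agreement is assessed on the
#' natural-log scale: for each matched lesion,
#' `r = ln(retest / test)` of the selected feature. The direction is fixed as
#' retest over test; only the sign of the bias depends on this choice.
#'
#' @param pairs Matched-pairs tibble (see [simulate_cohort()] /
#'   [measurements_to_pairs()]).
#' @param feature One of `"suv_max"`, `"suv_mean"`, `"suv_total"`,
#'   `"volume_cc"`.
#' @return A tibble with columns `patient_id`, `lesion_id`, `r`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_patients = 3, seed = 1))
#' log_ratios(cohort$pairs, "suv_max")
log_ratios <- function(pairs, feature = FEATURES) {
  feature <- match.arg(feature)
  check_pairs(pairs, feature)
  x1 <- pairs[[paste0(feature, "_test")]]
  x2 <- pairs[[paste0(feature, "_retest")]]
  bad <- !is.finite(x1) | !is.finite(x2) | x1 <= 0 | x2 <= 0
  if (any(bad)) {
    culprits <- paste(pairs$patient_id[bad], pairs$lesion_id[bad],
                      sep = "/", collapse = ", ")
    abort_validation(sprintf(
      "non-positive or non-finite %s value(s) for lesion(s): %s",
      feature, culprits))
  }
  tibble::tibble(patient_id = pairs$patient_id,
                 lesion_id = pairs$lesion_id,
                 r = log(x2 / x1))
}

#' Variance components of log-ratios with multiple lesions per patient
#'
#' Estimates the bias and spread of the test-retest log-ratios when patients
#' contribute multiple lesions and the true value differs between lesions.
#' The bias `d_bar` is the unweighted mean of `r` over all lesions. The
#' spread combines a one-way ANOVA with patients as groups: with `n` patients
#' and `N` lesions (patient i contributing `m_i`),
#' \deqn{MS_b = \sum_i m_i (\bar r_i - \bar d)^2 / (n - 1), \quad
#'       MS_w = \sum_i \sum_j (r_{ij} - \bar r_i)^2 / (N - n),}
#' \deqn{m_0 = (N - \sum_i m_i^2 / N) / (n - 1), \quad
#'       \hat\sigma^2_b = \max(0, (MS_b - MS_w) / m_0), \quad
#'       \sigma = \sqrt{\hat\sigma^2_b + MS_w}.}
#' The between-patient component is clamped at zero (method-of-moments
#' practice). With a single patient, or when every patient contributes a
#' single lesion (no within-patient information), the estimator collapses to
#' the ordinary sample SD of `r`.
#'
#' @param samples Log-ratio tibble from [log_ratios()] (columns `patient_id`,
#'   `r`; at least 2 rows).
#' @return An object of class `variance_components`: list with `d_bar`,
#'   `ms_between`, `ms_within`, `m0`, `var_between`, `sigma`, `n_patients`,
#'   `n_lesions`.
#' @export
variance_components <- function(samples) {
  if (!all(c("patient_id", "r") %in% names(samples))) {
    abort_structure("`samples` needs columns patient_id and r.")
  }
  r <- samples$r
  N <- length(r)
  if (N < 2L) {
    abort("at least 2 log-ratio samples are required.",
          class = "petrep_error_insufficient_data")
  }
  if (any(!is.finite(r))) abort_validation("log-ratios must be finite.")
  d_bar <- mean(r)
  grp <- dplyr::summarise(dplyr::group_by(samples, .data$patient_id),
                          m = dplyr::n(), r_bar = mean(.data$r),
                          ss_within = sum((.data$r - mean(.data$r))^2))
  n <- nrow(grp)
  if (n == 1L) {
    s <- sd(r)
    return(new_variance_components(
      d_bar, ms_between = NA_real_, ms_within = s^2, m0 = NA_real_,
      var_between = 0, sigma = s, n_patients = n, n_lesions = N))
  }
  ms_between <- sum(grp$m * (grp$r_bar - d_bar)^2) / (n - 1)
  # All-singleton grouping leaves zero within-group degrees of freedom; the
  # estimator then degenerates to the marginal SD (ms_within := 0 makes
  # var_between = var(r) via m0 = 1).
  ms_within <- if (N == n) 0 else sum(grp$ss_within) / (N - n)
  m0 <- (N - sum(grp$m^2) / N) / (n - 1)
  var_between <- max(0, (ms_between - ms_within) / m0)
  new_variance_components(d_bar, ms_between, ms_within, m0, var_between,
                          sigma = sqrt(var_between + ms_within),
                          n_patients = n, n_lesions = N)
}

new_variance_components <- function(d_bar, ms_between, ms_within, m0,
                                    var_between, sigma, n_patients, n_lesions) {
  structure(
    list(d_bar = d_bar, ms_between = ms_between, ms_within = ms_within,
         m0 = m0, var_between = var_between, sigma = sigma,
         n_patients = n_patients, n_lesions = n_lesions),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> d_bar = %.4g, sigma = %.4g (%d lesions, %d patients)\n",
    x$d_bar, x$sigma, x$n_lesions, x$n_patients))
  invisible(x)
}

#' @describeIn variance_components One-row tibble of all components.
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(d_bar = x$d_bar, ms_between = x$ms_between,
                 ms_within = x$ms_within, m0 = x$m0,
                 var_between = x$var_between, sigma = x$sigma,
                 n_patients = x$n_patients, n_lesions = x$n_lesions)
}

#' @describeIn variance_components One-row summary (bias, sigma, sizes).
#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(d_bar = x$d_bar, sigma = x$sigma,
                 n_patients = x$n_patients, n_lesions = x$n_lesions)
}

#' Back-transformed 95% limits of agreement
#'
#' Converts the log-scale bias and spread into percentage limits of
#' agreement: `95% LOA = exp(d_bar - 1.96 sigma), exp(d_bar + 1.96 sigma)`,
#' reported as percentage deviations from unity. The multiplier is fixed at
#' 1.96 (normal-theory 95% interval). Back-transformed bounds are
#' asymmetric: the lower bound can never fall below -100%.
#'
#' @param vc A [variance_components()] object (any list with numeric `d_bar`
#'   and `sigma` is accepted).
#' @return A one-row tibble with `bias_pct`, `loa_lower_pct`,
#'   `loa_upper_pct`.
#' @export
#' @examples
#' limits_of_agreement(list(d_bar = 0, sigma = 0.1))
limits_of_agreement <- function(vc) {
  if (!is.list(vc) || !is.numeric(vc$d_bar) || !is.numeric(vc$sigma)) {
    abort_structure("`vc` must provide numeric `d_bar` and `sigma`.")
  }
  tibble::tibble(
    bias_pct = 100 * (exp(vc$d_bar) - 1),
    loa_lower_pct = 100 * (exp(vc$d_bar - 1.96 * vc$sigma) - 1),
    loa_upper_pct = 100 * (exp(vc$d_bar + 1.96 * vc$sigma) - 1)
  )
}

#' Intraclass correlation of test and retest measurements
#'
#' Agreement between the two scans relative to between-lesion variance, on
#' the raw (untransformed) feature values, with lesions as subjects and the
#' two time points as the k = 2 repeated measurements. The default is the
#' two-way, absolute-agreement, single-measurement form
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the between-lesion,
#' between-scan and residual mean squares. `type = "one_way"` gives the
#' one-way random-effects form \eqn{(MS_R - MS_W)/(MS_R + (k-1) MS_W)}.
#'
#' @inheritParams log_ratios
#' @param type ICC variant.
#' @return A single numeric ICC in (-1, 1].
#' @export
icc <- function(pairs, feature = FEATURES,
                type = c("two_way_agreement", "one_way")) {
  feature <- match.arg(feature)
  type <- match.arg(type)
  check_pairs(pairs, feature)
  x1 <- pairs[[paste0(feature, "_test")]]
  x2 <- pairs[[paste0(feature, "_retest")]]
  n <- length(x1)
  if (n < 2L) {
    abort("at least 2 pairs are required for the ICC.",
          class = "petrep_error_insufficient_data")
  }
  if (any(!is.finite(x1)) || any(!is.finite(x2))) {
    abort_validation("feature values must be finite.")
  }
  k <- 2
  g <- mean(c(x1, x2))
  row_means <- (x1 + x2) / 2
  col_means <- c(mean(x1), mean(x2))
  ss_total <- sum((c(x1, x2) - g)^2)
  ss_rows <- k * sum((row_means - g)^2)
  if (ss_rows <= 0) {
    abort_validation("zero between-lesion variance; the ICC is undefined.")
  }
  ss_cols <- n * sum((col_means - g)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (type == "two_way_agreement") {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  } else {
    ms_w <- (ss_cols + ss_err) / (n * (k - 1))
    (ms_r - ms_w) / (ms_r + (k - 1) * ms_w)
  }
}

#' Within-subject coefficient of variation
#'
#' Within-pair spread relative to the pair mean, in percent. The default is
#' the root-mean-square of per-lesion CVs: for each lesion the within-pair SD
#' is `|x1 - x2| / sqrt(2)` and the CV is that SD over the pair mean;
#' `wCOV = 100 * sqrt(mean(CV^2))`. `method = "pooled_sd"` instead pools the
#' within-pair SDs and divides by the grand mean.
#'
#' @inheritParams log_ratios
#' @param method wCOV definition.
#' @return A single numeric percentage.
#' @export
wcov <- function(pairs, feature = FEATURES, method = c("rms_cv", "pooled_sd")) {
  feature <- match.arg(feature)
  method <- match.arg(method)
  check_pairs(pairs, feature)
  x1 <- pairs[[paste0(feature, "_test")]]
  x2 <- pairs[[paste0(feature, "_retest")]]
  if (any(!is.finite(x1) | !is.finite(x2) | x1 <= 0 | x2 <= 0)) {
    abort_validation(sprintf("non-positive %s value(s); wCOV undefined.",
                             feature))
  }
  within_var <- (x1 - x2)^2 / 2
  m <- (x1 + x2) / 2
  if (method == "rms_cv") {
    100 * sqrt(mean(within_var / m^2))
  } else {
    100 * sqrt(mean(within_var)) / mean(m)
  }
}

#' Exclude small lesions by a volume threshold
#'
#' Retains matched pairs whose lesion volume exceeds `threshold_cc` strictly.
#' A matched lesion carries two volume estimates; by default the mean of the
#' test and retest `volume_cc` is compared against the threshold
#' (`statistic = "test"` uses the test-scan volume alone).
#'
#' @inheritParams log_ratios
#' @param threshold_cc Non-negative volume threshold in cm^3.
#' @param statistic Which per-lesion volume summary to threshold.
#' @return The filtered pairs tibble.
#' @export
filter_by_volume <- function(pairs, threshold_cc,
                             statistic = c("mean", "test")) {
  statistic <- match.arg(statistic)
  if (!is.numeric(threshold_cc) || length(threshold_cc) != 1L ||
      !is.finite(threshold_cc) || threshold_cc < 0) {
    abort_params("`threshold_cc` must be a single non-negative number.")
  }
  check_pairs(pairs, "volume_cc")
  v <- switch(statistic,
              mean = (pairs$volume_cc_test + pairs$volume_cc_retest) / 2,
              test = pairs$volume_cc_test)
  pairs[v > threshold_cc, , drop = FALSE]
}

#' Stratified repeatability table
#'
#' The package's main result: for every feature and every volume stratum
#' ("all" plus one stratum per threshold, excluding lesions at or below the
#' threshold), runs [log_ratios()] -> [variance_components()] ->
#' [limits_of_agreement()] and adds [icc()] and [wcov()], yielding one row
#' per feature-stratum cell. All four features share each stratum's filtered
#' lesion set. Strata with fewer than two pairs are skipped with a warning.
#'
#' @inheritParams log_ratios
#' @param features Character vector of features to analyse.
#' @param thresholds_cc Numeric vector of volume thresholds in cm^3.
#' @param icc_type,wcov_method,volume_statistic Passed to [icc()], [wcov()]
#'   and [filter_by_volume()].
#' @return A tibble of class `repeatability_table` with columns `feature`,
#'   `stratum`, `n_lesions`, `bias_pct`, `loa_lower_pct`, `loa_upper_pct`,
#'   `icc`, `wcov_pct`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_params(seed = 7))
#' repeatability_table(cohort$pairs)
repeatability_table <- function(pairs,
                                features = FEATURES,
                                thresholds_cc = c(1, 1.5),
                                icc_type = c("two_way_agreement", "one_way"),
                                wcov_method = c("rms_cv", "pooled_sd"),
                                volume_statistic = c("mean", "test")) {
  icc_type <- match.arg(icc_type)
  wcov_method <- match.arg(wcov_method)
  volume_statistic <- match.arg(volume_statistic)
  features <- match.arg(features, choices = FEATURES, several.ok = TRUE)
  if (nrow(pairs) == 0L) abort_validation("`pairs` is empty.")
  check_pairs(pairs)

  strata <- c(list(all = pairs),
              setNames(
                lapply(thresholds_cc, function(th) {
                  filter_by_volume(pairs, th, statistic = volume_statistic)
                }),
                sprintf(">%g cm3", thresholds_cc)))

  rows <- purrr::imap(strata, function(sub, label) {
    if (nrow(sub) < 2L) {
      warn(sprintf("stratum '%s' has %d pair(s); skipped.", label, nrow(sub)))
      return(NULL)
    }
    purrr::map(features, function(f) {
      vc <- variance_components(log_ratios(sub, f))
      loa <- limits_of_agreement(vc)
      tibble::tibble(
        feature = f, stratum = label, n_lesions = nrow(sub),
        bias_pct = loa$bias_pct,
        loa_lower_pct = loa$loa_lower_pct,
        loa_upper_pct = loa$loa_upper_pct,
        icc = icc(sub, f, type = icc_type),
        wcov_pct = wcov(sub, f, method = wcov_method)
      )
    })
  })
  prototype <- tibble::tibble(
    feature = character(), stratum = character(), n_lesions = integer(),
    bias_pct = numeric(), loa_lower_pct = numeric(),
    loa_upper_pct = numeric(), icc = numeric(), wcov_pct = numeric())
  out <- dplyr::bind_rows(c(list(prototype), purrr::flatten(rows)))
  class(out) <- c("repeatability_table", class(out))
  out
}

#' @describeIn repeatability_table Dot-and-whisker plot of bias and LOA per
#'   feature and stratum.
#' @param object A `repeatability_table`.
#' @param ... Unused.
#' @method autoplot repeatability_table
#' @export
autoplot.repeatability_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$stratum, y = .data$bias_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$loa_lower_pct,
                                          ymax = .data$loa_upper_pct)) +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "volume stratum",
                  y = "retest/test deviation (%), bias and 95% LOA") +
    ggplot2::theme_minimal()
}
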