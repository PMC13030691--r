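# Per-patient truth draws, shared by table and phantom mode. Everything for
# patient i is drawn under its own derived seed, in a fixed order, so the two
# modes agree on the ground truth and cohorts are extensible without
# perturbing earlier patients.
draw_patient_truth <- function(params, patient_index) {
  set.seed(patient_seed(params$seed, patient_index))
  m <- max(1L, rpois(1L, params$lesions_per_patient_mean))
  log_volume <- rnorm(m, params$log_volume_mean, params$log_volume_sd)
  log_uptake <- rnorm(m, params$log_uptake_mean, params$log_uptake_sd)
  # SUVmax sits above SUVmean by a lesion-specific peak-to-mean factor.
  peak_factor <- runif(m, 1.2, 2.0)
  bias <- rnorm(1L, 0, params$patient_bias_sd)
  list(
    patient_id = sprintf("P%02d", patient_index),
    m = m,
    log_volume = log_volume,
    log_uptake = log_uptake,
    log_suv_max = log_uptake + log(peak_factor),
    bias = bias
  )
}

#' Simulate a matched test-retest lesion feature table
#'
#' Generates a cohort of matched lesion pairs directly on the feature-table
#' level. For every lesion, the test measurement of each primitive feature
#' (SUVmax, SUVmean, volume) is its true value perturbed by independent
#' lognormal noise with log-SD `lesion_noise_sd`; the retest measurement is
#' additionally multiplied by the patient's shared bias factor
#' `exp(bias)` with `bias ~ N(0, patient_bias_sd^2)`. SUVtotal is
#' `suv_mean * volume_cc` by construction at both time points, so its
#' log-ratio compounds the bias and noise of both factors.
#'
#' @param params A [cohort_params()] object.
#' @return A list with components:
#'   * `pairs`: tibble of matched pairs, one row per lesion, with columns
#'     `patient_id`, `lesion_id` and `<feature>_test` / `<feature>_retest`
#'     for the four features.
#'   * `truth`: tibble of generative ground truth (`log_volume_true`,
#'     `log_uptake_true`, `log_suv_max_true`, `patient_bias`), one row per
#'     lesion, for parameter-recovery tests.
#'   * `params`: the parameters used.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_patients = 3, seed = 42))
#' head(cohort$pairs)
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    abort_params("`params` must be a `cohort_params` object.")
  }
  rows <- vector("list", params$n_patients)
  truths <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    tr <- draw_patient_truth(params, i)
    m <- tr$m
    # Noise draws: one per primitive feature, per scan, per lesion, in a
    # fixed order within the patient's stream.
    eps <- array(rnorm(m * 3L * 2L, 0, params$lesion_noise_sd),
                 dim = c(m, 3L, 2L))
    true_log <- cbind(tr$log_suv_max, tr$log_uptake, tr$log_volume)
    test <- exp(true_log + eps[, , 1L])
    retest <- exp(true_log + tr$bias + eps[, , 2L])
    lesion_id <- sprintf("%s_L%03d", tr$patient_id, seq_len(m))
    rows[[i]] <- tibble::tibble(
      patient_id = tr$patient_id,
      lesion_id = lesion_id,
      suv_max_test = test[, 1L], suv_max_retest = retest[, 1L],
      suv_mean_test = test[, 2L], suv_mean_retest = retest[, 2L],
      suv_total_test = test[, 2L] * test[, 3L],
      suv_total_retest = retest[, 2L] * retest[, 3L],
      volume_cc_test = test[, 3L], volume_cc_retest = retest[, 3L]
    )
    truths[[i]] <- tibble::tibble(
      patient_id = tr$patient_id,
      lesion_id = lesion_id,
      log_volume_true = tr$log_volume,
      log_uptake_true = tr$log_uptake,
      log_suv_max_true = tr$log_suv_max,
      patient_bias = tr$bias
    )
  }
  list(
    pairs = dplyr::bind_rows(rows),
    truth = dplyr::bind_rows(truths),
    params = params
  )
}

#' Convert between matched-pair and long measurement tables
#'
#' The long ("measurement") layout has one row per lesion per time point with
#' columns `patient_id, lesion_id, timepoint, suv_max, suv_mean, suv_total,
#' volume_cc` — the same schema as the feature CSV written by
#' [write_measurements_csv()]. The wide ("pairs") layout has one row per
#' matched lesion with `_test`/`_retest` suffixed feature columns and is what
#' the repeatability statistics consume.
#'
#' @param pairs A matched-pairs tibble.
#' @return `pairs_to_measurements()`: a long measurement tibble.
#' @export
pairs_to_measurements <- function(pairs) {
  check_pairs(pairs)
  long <- tidyr::pivot_longer(
    pairs,
    cols = dplyr::ends_with(c("_test", "_retest")),
    names_to = c(".value", "timepoint"),
    names_pattern = "^(.*)_(test|retest)$"
  )
  dplyr::select(long, "patient_id", "lesion_id", "timepoint",
                "suv_max", "suv_mean", "suv_total", "volume_cc")
}

#' @rdname pairs_to_measurements
#' @param measurements A long measurement tibble; every lesion must appear at
#'   exactly the two time points `"test"` and `"retest"`.
#' @return `measurements_to_pairs()`: a matched-pairs tibble.
#' @export
measurements_to_pairs <- function(measurements) {
  need <- c("patient_id", "lesion_id", "timepoint",
            "suv_max", "suv_mean", "suv_total", "volume_cc")
  missing <- setdiff(need, names(measurements))
  if (length(missing) > 0) {
    abort_structure(paste0("measurement table lacks column(s): ",
                           paste(missing, collapse = ", ")))
  }
  bad_tp <- setdiff(unique(measurements$timepoint), c("test", "retest"))
  if (length(bad_tp) > 0) {
    abort_validation(paste0("unknown timepoint value(s): ",
                            paste(bad_tp, collapse = ", ")))
  }
  counts <- dplyr::count(measurements, .data$patient_id, .data$lesion_id,
                         .data$timepoint)
  if (any(counts$n != 1L)) {
    abort_validation("duplicated (patient, lesion, timepoint) rows.")
  }
  wide <- tidyr::pivot_wider(
    measurements,
    id_cols = c("patient_id", "lesion_id"),
    names_from = "timepoint",
    values_from = c("suv_max", "suv_mean", "suv_total", "volume_cc"),
    names_glue = "{.value}_{timepoint}"
  )
  incomplete <- !stats::complete.cases(wide)
  if (any(incomplete)) {
    warn(sprintf("dropping %d lesion(s) without both time points.",
                 sum(incomplete)))
    wide <- wide[!incomplete, , drop = FALSE]
  }
  dplyr::select(wide, "patient_id", "lesion_id",
                dplyr::all_of(paste0(rep(FEATURES, each = 2L),
                                     c("_test", "_retest"))))
}

check_pairs <- function(pairs, features = FEATURES) {
  need <- c("patient_id", "lesion_id",
            paste0(rep(features, each = 2L), c("_test", "_retest")))
  missing <- setdiff(need, names(pairs))
  if (length(missing) > 0) {
    abort_structure(paste0("pair table lacks column(s): ",
                           paste(missing, collapse = ", ")))
  }
  invisible(pairs)
}
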