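#' Parameters of the synthetic test-retest cohort
#'
#' Bundles and validates every generative knob of the synthetic cohort. The
#' defaults emulate the structure of a typical PSMA-PET test-retest study:
#' 22 patients contributing on average 13.5 lesions each (about 300 matched
#' lesions), lognormal lesion volumes calibrated so that roughly 64% exceed
#' 1 cm^3 and 54% exceed 1.5 cm^3, a shared multiplicative per-patient
#' retest/test bias, and independent per-lesion lognormal measurement noise.
#'
#' All noise is multiplicative (normal on the natural-log scale), which makes
#' the limits-of-agreement estimand analytically known: the log-ratio of a
#' matched pair has standard deviation `sqrt(patient_bias_sd^2 +
#' 2 * lesion_noise_sd^2)` for each primitive feature.
#'
#' @param n_patients Number of patients (>= 1).
#' @param lesions_per_patient_mean Poisson mean of lesions per patient; a
#'   minimum of one lesion per patient is enforced.
#' @param log_volume_mean,log_volume_sd Mean and SD of true lesion volume on
#'   the natural-log cm^3 scale.
#' @param log_uptake_mean,log_uptake_sd Mean and SD of true lesion SUVmean on
#'   the natural-log scale (SUV is dimensionless, g/mL).
#' @param patient_bias_sd SD (log scale) of the per-patient retest/test bias
#'   shared by all of a patient's lesions; often written tau.
#' @param lesion_noise_sd SD (log scale) of the independent per-lesion,
#'   per-feature, per-scan measurement noise; often written sigma_w.
#' @param jitter_boundary_prob Probability, in phantom mode, that each ROI
#'   boundary voxel is independently flipped (eroded or dilated) on the retest
#'   mask, emulating segmentation variability.
#' @param voxel_size_mm Length-3 positive voxel dimensions in mm (phantom mode).
#' @param grid_shape Length-3 integer grid dimensions (phantom mode).
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output. The stream is split per patient, so enlarging the cohort does not
#'   perturb earlier patients.
#'
#' @return An object of class `cohort_params` (a validated named list).
#' @seealso [simulate_cohort()], [simulate_phantom_pair()]
#' @export
#' @examples
#' p <- cohort_params(n_patients = 4, lesions_per_patient_mean = 3, seed = 7)
#' cohort <- simulate_cohort(p)
#' nrow(cohort$pairs)
cohort_params <- function(n_patients = 22,
                          lesions_per_patient_mean = 13.5,
                          log_volume_mean = 0.57,
                          log_volume_sd = 1.55,
                          log_uptake_mean = 1.6,
                          log_uptake_sd = 0.7,
                          patient_bias_sd = 0.10,
                          lesion_noise_sd = 0.09,
                          jitter_boundary_prob = 0.2,
                          voxel_size_mm = c(2, 2, 2),
                          grid_shape = c(64L, 64L, 64L),
                          seed = 1L) {
  chk_num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort_params(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  chk_num1(n_patients, "n_patients")
  if (n_patients < 1) abort_params("`n_patients` must be >= 1.")
  chk_num1(lesions_per_patient_mean, "lesions_per_patient_mean")
  if (lesions_per_patient_mean <= 0) {
    abort_params("`lesions_per_patient_mean` must be positive.")
  }
  for (nm in c("log_volume_mean", "log_volume_sd", "log_uptake_mean",
               "log_uptake_sd", "patient_bias_sd", "lesion_noise_sd",
               "jitter_boundary_prob", "seed")) {
    chk_num1(get(nm), nm)
  }
  for (nm in c("log_volume_sd", "log_uptake_sd", "patient_bias_sd",
               "lesion_noise_sd")) {
    if (get(nm) < 0) abort_params(sprintf("`%s` must be >= 0.", nm))
  }
  if (jitter_boundary_prob < 0 || jitter_boundary_prob > 1) {
    abort_params("`jitter_boundary_prob` must be in [0, 1].")
  }
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 3L ||
      any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0)) {
    abort_params("`voxel_size_mm` must be three positive numbers.")
  }
  if (!is.numeric(grid_shape) || length(grid_shape) != 3L ||
      any(grid_shape < 4) || any(grid_shape != round(grid_shape))) {
    abort_params("`grid_shape` must be three integers >= 4.")
  }

  structure(
    list(
      n_patients = as.integer(n_patients),
      lesions_per_patient_mean = lesions_per_patient_mean,
      log_volume_mean = log_volume_mean,
      log_volume_sd = log_volume_sd,
      log_uptake_mean = log_uptake_mean,
      log_uptake_sd = log_uptake_sd,
      patient_bias_sd = patient_bias_sd,
      lesion_noise_sd = lesion_noise_sd,
      jitter_boundary_prob = jitter_boundary_prob,
      voxel_size_mm = as.numeric(voxel_size_mm),
      grid_shape = as.integer(grid_shape),
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat(sprintf("  %d patients, ~%.1f lesions/patient (Poisson, min 1)\n",
              x$n_patients, x$lesions_per_patient_mean))
  cat(sprintf("  log-volume N(%.3g, %.3g^2) [ln cm^3], log-uptake N(%.3g, %.3g^2)\n",
              x$log_volume_mean, x$log_volume_sd,
              x$log_uptake_mean, x$log_uptake_sd))
  cat(sprintf("  patient bias SD tau = %.3g, lesion noise SD sigma_w = %.3g (log scale)\n",
              x$patient_bias_sd, x$lesion_noise_sd))
  cat(sprintf("  phantom: grid %s, voxel %s mm, boundary jitter p = %.3g, seed %d\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              x$jitter_boundary_prob, x$seed))
  invisible(x)
}
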