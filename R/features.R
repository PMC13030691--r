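#' Construct a labeled SUV image
#'
#' Couples an SUV volume with its integer lesion label mask and the metadata
#' the feature extractor needs. SUV is dimensionless (g/mL); label 0 is
#' background and each positive integer one lesion ROI.
#'
#' @param suv 3-D numeric array of SUV values.
#' @param labels 3-D array of non-negative integer labels, same shape.
#' @param voxel_size_mm Length-3 positive voxel dimensions in mm.
#' @param patient_id Patient identifier.
#' @param timepoint `"test"` or `"retest"`.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(suv, labels, voxel_size_mm,
                          patient_id = "P01", timepoint = c("test", "retest")) {
  timepoint <- match.arg(timepoint)
  if (!is.array(suv) || length(dim(suv)) != 3L) {
    abort_structure("`suv` must be a 3-D array.")
  }
  if (!is.array(labels) || !identical(dim(labels), dim(suv))) {
    abort_structure("`labels` must be a 3-D array with the same shape as `suv`.")
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    abort_structure("`labels` must contain non-negative integers.")
  }
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 3L ||
      any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0)) {
    abort_structure("`voxel_size_mm` must be three positive numbers.")
  }
  structure(
    list(suv = suv, labels = labels,
         voxel_size_mm = as.numeric(voxel_size_mm),
         patient_id = as.character(patient_id), timepoint = timepoint),
    class = "labeled_image"
  )
}

#' Extract lesion uptake features from a labeled SUV image
#'
#' Computes, for every distinct non-zero label, the four standard lesion
#' uptake features: `suv_max` (maximum SUV over the ROI voxels), `suv_mean`
#' (arithmetic mean), `volume_cc` (voxel count times voxel volume, converted
#' mm^3 to cm^3), and `suv_total` (sum of ROI SUVs times voxel volume in
#' cm^3, the analog of total lesion glycolysis). By construction
#' `suv_total == suv_mean * volume_cc` to floating tolerance.
#'
#' @param image A [labeled_image()].
#' @return A tibble with one row per lesion and columns `patient_id`,
#'   `lesion_id` (the integer label), `timepoint`, `suv_max`, `suv_mean`,
#'   `suv_total`, `volume_cc`. An all-background mask yields an empty tibble
#'   with a warning.
#' @export
#' @examples
#' suv <- array(2, dim = c(2, 2, 2))
#' lab <- array(1L, dim = c(2, 2, 2))
#' extract_features(labeled_image(suv, lab, c(4, 4, 4)))
extract_features <- function(image) {
  if (!inherits(image, "labeled_image")) {
    abort_structure("`image` must be a `labeled_image` object.")
  }
  sel <- image$labels > 0
  empty <- tibble::tibble(
    patient_id = character(), lesion_id = integer(), timepoint = character(),
    suv_max = numeric(), suv_mean = numeric(), suv_total = numeric(),
    volume_cc = numeric()
  )
  if (!any(sel)) {
    warn(sprintf("image %s/%s has an empty label mask; no features extracted.",
                 image$patient_id, image$timepoint))
    return(empty)
  }
  v <- image$suv[sel]
  if (any(!is.finite(v))) {
    abort_validation("non-finite SUV values inside labeled ROIs; corrupt input.")
  }
  g <- factor(image$labels[sel])
  vox_cc <- prod(image$voxel_size_mm) / 1000
  n_vox <- as.integer(tapply(v, g, length))
  tibble::tibble(
    patient_id = image$patient_id,
    lesion_id = as.integer(levels(g)),
    timepoint = image$timepoint,
    suv_max = as.numeric(tapply(v, g, max)),
    suv_mean = as.numeric(tapply(v, g, mean)),
    suv_total = as.numeric(tapply(v, g, sum)) * vox_cc,
    volume_cc = n_vox * vox_cc
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %s/%s: grid %s, voxel %s mm, %d lesion label(s)\n",
              x$patient_id, x$timepoint, paste(dim(x$suv), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              length(setdiff(unique(as.vector(x$labels)), 0))))
  invisible(x)
}
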