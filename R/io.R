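#' Read a labeled SUV image from NIfTI files
#'
#' Reads an SUV volume and its integer label mask from NIfTI (.nii/.nii.gz),
#' taking voxel dimensions from the SUV image header.
#'
#' @param suv_path,labels_path Paths to the SUV and label NIfTI files.
#' @inheritParams labeled_image
#' @return A [labeled_image()].
#' @export
read_labeled_image <- function(suv_path, labels_path,
                               patient_id = "P01",
                               timepoint = c("test", "retest")) {
  timepoint <- match.arg(timepoint)
  for (p in c(suv_path, labels_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p),
                               class = "petrep_error_io")
  }
  suv <- RNifti::readNifti(suv_path)
  lab <- RNifti::readNifti(labels_path)
  vs <- RNifti::pixdim(suv)[1:3]
  labeled_image(array(as.numeric(suv), dim = dim(suv)),
                array(as.integer(round(lab)), dim = dim(lab)),
                voxel_size_mm = vs, patient_id = patient_id,
                timepoint = timepoint)
}

#' Write a phantom pair to NIfTI files
#'
#' Writes the four volumes of a [simulate_phantom_pair()] result (SUV and
#' label image per time point) as compressed NIfTI, plus the ground-truth and
#' label-correspondence tables as CSV.
#'
#' @param phantom A `phantom_pair`.
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix; defaults to the patient id.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_phantom_pair <- function(phantom, dir, prefix = phantom$patient_id) {
  if (!inherits(phantom, "phantom_pair")) {
    abort_structure("`phantom` must be a `phantom_pair` object.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(arr, name, integer = FALSE) {
    img <- RNifti::asNifti(if (integer) array(as.integer(arr), dim(arr)) else arr)
    RNifti::pixdim(img) <- phantom$voxel_size_mm
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, name))
    RNifti::writeNifti(img, path, datatype = if (integer) "int32" else "double")
    path
  }
  files <- c(
    suv_test = put(phantom$suv_test, "suv_test"),
    labels_test = put(phantom$labels_test, "labels_test", integer = TRUE),
    suv_retest = put(phantom$suv_retest, "suv_retest"),
    labels_retest = put(phantom$labels_retest, "labels_retest", integer = TRUE)
  )
  truth_path <- file.path(dir, sprintf("%s_truth.csv", prefix))
  readr::write_csv(phantom$truth, truth_path)
  map_path <- file.path(dir, sprintf("%s_label_map.csv", prefix))
  readr::write_csv(phantom$label_map, map_path)
  invisible(c(files, truth = truth_path, label_map = map_path))
}

#' Read and write the lesion feature CSV
#'
#' The feature CSV is the long measurement table with columns exactly
#' `patient_id, lesion_id, timepoint, suv_max, suv_mean, suv_total,
#' volume_cc` (comma-separated, UTF-8, header row, `.` decimal).
#'
#' @param measurements A long measurement tibble (see
#'   [pairs_to_measurements()]).
#' @param path File path.
#' @return `write_measurements_csv()` returns `path` invisibly;
#'   `read_measurements_csv()` returns the measurement tibble.
#' @export
write_measurements_csv <- function(measurements, path) {
  need <- c("patient_id", "lesion_id", "timepoint",
            "suv_max", "suv_mean", "suv_total", "volume_cc")
  missing <- setdiff(need, names(measurements))
  if (length(missing) > 0) {
    abort_structure(paste0("measurement table lacks column(s): ",
                           paste(missing, collapse = ", ")))
  }
  readr::write_csv(measurements[need], path)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                class = "petrep_error_io")
  readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      lesion_id = readr::col_character(),
      timepoint = readr::col_character(),
      suv_max = readr::col_double(),
      suv_mean = readr::col_double(),
      suv_total = readr::col_double(),
      volume_cc = readr::col_double()
    )
  )
}
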