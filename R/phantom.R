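# Voxelize an axis-aligned ellipsoid of volume exp(log_volume) cm^3 centred at
# `center` (voxel index units, fractional allowed). Returns integer index
# matrix of voxels whose centers fall inside.
voxelize_ellipsoid <- function(center, log_volume_cc, axis_factors,
                               voxel_size_mm, grid_shape) {
  r0 <- (3 * exp(log_volume_cc) * 1000 / (4 * pi))^(1 / 3)  # mm
  semi <- r0 * axis_factors                                  # mm, product-preserving
  half <- ceiling(semi / voxel_size_mm) + 1L
  lo <- pmax(1L, floor(center - half))
  hi <- pmin(grid_shape, ceiling(center + half))
  if (any(lo > hi)) return(matrix(integer(0), ncol = 3L))
  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2]); kk <- seq.int(lo[3], hi[3])
  grid <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  # voxel-center physical offsets from the ellipsoid center
  d <- sweep(grid, 2L, center, "-")
  d <- sweep(d, 2L, voxel_size_mm, "*")
  inside <- rowSums(sweep(d, 2L, semi, "/")^2) <= 1
  grid[inside, , drop = FALSE]
}

shift_mask <- function(mask, axis, by) {
  d <- dim(mask)
  n <- d[axis]
  out <- array(FALSE, dim = d)
  if (abs(by) >= n) return(out)
  to <- lapply(d, seq_len)
  from <- lapply(d, seq_len)
  to[[axis]] <- seq_len(n - abs(by)) + max(0L, by)
  from[[axis]] <- seq_len(n - abs(by)) + max(0L, -by)
  val <- do.call(`[`, c(list(mask), from, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), to, list(val)))
}

# TRUE where `mask` has at least one 6-connected neighbor in `other`.
adjacent_to <- function(mask, other) {
  adj <- array(FALSE, dim = dim(other))
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    adj <- adj | shift_mask(other, axis, by)
  }
  mask & adj
}

#' Simulate one patient's paired phantom scans
#'
#' Builds a voxelized test/retest image pair for one synthetic patient: each
#' lesion is an axis-aligned ellipsoid of uniform SUV plateau on a constant
#' low background. The retest label mask is the test mask with every ROI
#' boundary voxel (6-connectivity) independently flipped — eroded from the
#' lesion or dilated into the background — with probability
#' `jitter_boundary_prob`, mimicking segmentation variability whose relative
#' impact on volume grows as lesions shrink. Plateau values carry the same
#' patient bias and lesion noise as table mode ([simulate_cohort()]), and the
#' lesion ground truth (volumes, uptakes, bias) is identical to table mode for
#' the same `params` and `patient_index`.
#'
#' @param params A [cohort_params()] object.
#' @param patient_index Positive integer; which patient of the cohort.
#' @param min_center_separation_mm Minimum Euclidean distance between lesion
#'   centers, in mm (useful for matching studies; default 0 only enforces
#'   non-overlapping bounding boxes).
#' @param max_attempts Placement retries per lesion before failing.
#' @return An object of class `phantom_pair`: a list with `suv_test`,
#'   `labels_test`, `suv_retest`, `labels_retest` (3-D arrays),
#'   `voxel_size_mm`, `patient_id`, `truth` (per-lesion tibble incl. plateau
#'   values and voxelized volumes) and `label_map` (tibble of corresponding
#'   test/retest labels).
#' @export
simulate_phantom_pair <- function(params, patient_index,
                                  min_center_separation_mm = 0,
                                  max_attempts = 200L) {
  if (!inherits(params, "cohort_params")) {
    abort_params("`params` must be a `cohort_params` object.")
  }
  if (patient_index < 1 || patient_index != round(patient_index)) {
    abort_params("`patient_index` must be a positive integer.")
  }
  tr <- draw_patient_truth(params, patient_index)
  m <- tr$m
  gs <- params$grid_shape
  vs <- params$voxel_size_mm
  labels <- array(0L, dim = gs)

  # Fixed draw order after the truth block: placement, then plateau noise,
  # then jitter, so phantom output is reproducible from the same stream.
  axis_factors <- matrix(exp(rnorm(3L * m, 0, 0.15)), nrow = m)
  axis_factors <- axis_factors / exp(rowMeans(log(axis_factors)))  # product 1

  centers <- matrix(NA_real_, nrow = m, ncol = 3L)
  vox_list <- vector("list", m)
  for (l in seq_len(m)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      center <- runif(3L, min = 2, max = gs - 1)
      vox <- voxelize_ellipsoid(center, tr$log_volume[l], axis_factors[l, ],
                                vs, gs)
      if (nrow(vox) == 0L) next
      # keep 1 voxel of clearance so dilation jitter cannot merge lesions
      box_lo <- pmax(1L, apply(vox, 2L, min) - 1L)
      box_hi <- pmin(gs, apply(vox, 2L, max) + 1L)
      region <- labels[box_lo[1]:box_hi[1], box_lo[2]:box_hi[2],
                       box_lo[3]:box_hi[3]]
      if (any(region != 0L)) next
      if (min_center_separation_mm > 0 && l > 1L) {
        prev <- centers[seq_len(l - 1L), , drop = FALSE]
        dmm <- sqrt(colSums((t(prev) - center)^2 * vs^2))
        if (any(dmm < min_center_separation_mm)) next
      }
      labels[vox] <- l
      centers[l, ] <- center
      vox_list[[l]] <- vox
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf(
        "could not place lesion %d (true volume %.2f cm^3) after %d attempts on a %s grid.",
        l, exp(tr$log_volume[l]), max_attempts, paste(gs, collapse = "x")),
        class = "petrep_error_placement")
    }
  }

  # Plateau SUVs: test = truth * lesion noise; retest adds the patient bias.
  eps <- matrix(rnorm(2L * m, 0, params$lesion_noise_sd), ncol = 2L)
  plateau_test <- exp(tr$log_uptake + eps[, 1L])
  plateau_retest <- exp(tr$log_uptake + tr$bias + eps[, 2L])

  labels_retest <- jitter_labels(labels, params$jitter_boundary_prob)

  background <- 0.1
  suv_test <- array(background, dim = gs)
  suv_retest <- array(background, dim = gs)
  for (l in seq_len(m)) {
    suv_test[labels == l] <- plateau_test[l]
    suv_retest[labels_retest == l] <- plateau_retest[l]
  }

  truth <- tibble::tibble(
    patient_id = tr$patient_id,
    lesion = seq_len(m),
    log_volume_true = tr$log_volume,
    log_uptake_true = tr$log_uptake,
    patient_bias = tr$bias,
    plateau_test = plateau_test,
    plateau_retest = plateau_retest,
    volume_vox_test_cc = vapply(seq_len(m), function(l) sum(labels == l),
                                0L) * prod(vs) / 1000,
    volume_vox_retest_cc = vapply(seq_len(m), function(l) sum(labels_retest == l),
                                  0L) * prod(vs) / 1000
  )

  structure(
    list(
      suv_test = suv_test, labels_test = labels,
      suv_retest = suv_retest, labels_retest = labels_retest,
      voxel_size_mm = vs, patient_id = tr$patient_id,
      truth = truth,
      label_map = tibble::tibble(label_test = seq_len(m),
                                 label_retest = seq_len(m))
    ),
    class = "phantom_pair"
  )
}

# Independently flip each ROI boundary voxel with probability p: inner
# boundary voxels may be dropped to background, background voxels adjacent to
# the ROI may be annexed. Each lesion retains at least one voxel.
jitter_labels <- function(labels, p) {
  if (p <= 0) return(labels)
  out <- labels
  for (l in sort(unique(labels[labels > 0L]))) {
    mask <- labels == l
    inner <- adjacent_to(mask, !mask)
    outer <- adjacent_to(labels == 0L, mask)
    rm_idx <- which(inner)
    add_idx <- which(outer & out == 0L)
    drop <- rm_idx[runif(length(rm_idx)) < p]
    add <- add_idx[runif(length(add_idx)) < p]
    keep_mask <- mask
    keep_mask[drop] <- FALSE
    if (!any(keep_mask)) {
      # keep the voxel closest to the ROI centroid
      ind <- which(mask, arr.ind = TRUE)
      cen <- colMeans(ind)
      d2 <- rowSums(sweep(ind, 2L, cen, "-")^2)
      keep_mask[ind[which.min(d2), , drop = FALSE]] <- TRUE
    }
    out[mask & !keep_mask] <- 0L
    out[add] <- l
  }
  out
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> patient %s: %d lesion(s), grid %s, voxel %s mm\n",
              x$patient_id, nrow(x$truth),
              paste(dim(x$labels_test), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}
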