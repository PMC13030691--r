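#' Physical-space centroids of every lesion ROI
#'
#' Returns the mean position of each ROI's voxel centers in mm, using the
#' voxel-center convention: voxel at (1-based) index `(i, j, k)` has its
#' center at `((i - 1/2) dx, (j - 1/2) dy, (k - 1/2) dz)`.
#'
#' @param image A [labeled_image()].
#' @return A tibble with columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @export
compute_centroids <- function(image) {
  if (!inherits(image, "labeled_image")) {
    abort_structure("`image` must be a `labeled_image` object.")
  }
  labs <- sort(setdiff(unique(as.vector(image$labels)), 0))
  if (length(labs) == 0L) abort_validation("label mask is empty.")
  vs <- image$voxel_size_mm
  cen <- t(vapply(labs, function(l) {
    ind <- which(image$labels == l, arr.ind = TRUE)
    colMeans(sweep(ind - 0.5, 2L, vs, "*"))
  }, numeric(3)))
  tibble::tibble(label = as.integer(labs),
                 x_mm = cen[, 1L], y_mm = cen[, 2L], z_mm = cen[, 3L])
}

#' Match lesions across time points by centroid proximity
#'
#' Greedy mutual-nearest matching standing in for registration-based lesion
#' tracking: repeatedly take the globally closest unmatched test/retest
#' centroid pair with distance at most `max_distance_mm`, record it, and
#' remove both lesions from further consideration. Ties are broken by the
#' smaller test label, then the smaller retest label. Remaining lesions are
#' reported unmatched and are excluded from downstream repeatability
#' statistics.
#'
#' @param test_centroids,retest_centroids Centroid tibbles from
#'   [compute_centroids()].
#' @param max_distance_mm Positive matching radius in mm (default 10).
#' @param retest_affine Optional 4x4 affine applied to retest centroids
#'   before matching (a pre-computed rigid registration); default identity.
#' @return An object of class `lesion_match`: list with `matched` (tibble of
#'   `test_label`, `retest_label`, `centroid_distance_mm`), `unmatched_test`
#'   and `unmatched_retest` (integer vectors).
#' @export
match_lesions <- function(test_centroids, retest_centroids,
                          max_distance_mm = 10, retest_affine = NULL) {
  if (!is.numeric(max_distance_mm) || length(max_distance_mm) != 1L ||
      !is.finite(max_distance_mm) || max_distance_mm <= 0) {
    abort_params("`max_distance_mm` must be a single positive number.")
  }
  for (tab in list(test_centroids, retest_centroids)) {
    need <- c("label", "x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(tab))) {
      abort_structure("centroid tables need columns label, x_mm, y_mm, z_mm.")
    }
    if (nrow(tab) > 0 &&
        any(!is.finite(as.matrix(tab[, c("x_mm", "y_mm", "z_mm")])))) {
      abort_validation("centroid coordinates must be finite.")
    }
  }
  a <- as.matrix(test_centroids[, c("x_mm", "y_mm", "z_mm")])
  b <- as.matrix(retest_centroids[, c("x_mm", "y_mm", "z_mm")])
  if (!is.null(retest_affine)) {
    if (!is.matrix(retest_affine) || !all(dim(retest_affine) == c(4L, 4L))) {
      abort_params("`retest_affine` must be a 4x4 matrix.")
    }
    b <- t((retest_affine %*% rbind(t(b), 1))[1:3, , drop = FALSE])
  }
  la <- as.integer(test_centroids$label)
  lb <- as.integer(retest_centroids$label)

  matched <- tibble::tibble(test_label = integer(), retest_label = integer(),
                            centroid_distance_mm = numeric())
  if (nrow(a) > 0 && nrow(b) > 0) {
    d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      sqrt(rowSums((a[i, , drop = FALSE] - b[j, , drop = FALSE])^2))
    })
    free_a <- rep(TRUE, nrow(a))
    free_b <- rep(TRUE, nrow(b))
    repeat {
      dd <- d
      dd[!free_a, ] <- Inf
      dd[, !free_b] <- Inf
      if (all(!is.finite(dd)) || min(dd) > max_distance_mm) break
      cand <- which(dd == min(dd), arr.ind = TRUE)
      # deterministic tie-break: smallest test label, then retest label
      ord <- order(la[cand[, 1L]], lb[cand[, 2L]])
      i <- cand[ord[1L], 1L]
      j <- cand[ord[1L], 2L]
      matched <- dplyr::bind_rows(matched, tibble::tibble(
        test_label = la[i], retest_label = lb[j],
        centroid_distance_mm = d[i, j]))
      free_a[i] <- FALSE
      free_b[j] <- FALSE
    }
  }
  structure(
    list(matched = matched,
         unmatched_test = la[!la %in% matched$test_label],
         unmatched_retest = lb[!lb %in% matched$retest_label],
         max_distance_mm = max_distance_mm),
    class = "lesion_match"
  )
}

#' @export
print.lesion_match <- function(x, ...) {
  cat(sprintf("<lesion_match> %d matched pair(s), %d/%d unmatched (test/retest), radius %g mm\n",
              nrow(x$matched), length(x$unmatched_test),
              length(x$unmatched_retest), x$max_distance_mm))
  invisible(x)
}

#' @describeIn match_lesions Tidy the matched pairs into a tibble, with
#'   unmatched labels attached as attributes.
#' @param x A `lesion_match` object.
#' @param ... Unused.
#' @method tidy lesion_match
#' @export
tidy.lesion_match <- function(x, ...) {
  out <- x$matched
  attr(out, "unmatched_test") <- x$unmatched_test
  attr(out, "unmatched_retest") <- x$unmatched_retest
  out
}
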