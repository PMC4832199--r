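## Clinical morphological features from binary lesion/nodule masks: area and
## moment-matched ellipse major axis for 2-D lesions; volume, maximum
## per-slice major diameter and maximum slice area for nodule stacks.

#' Area, centroid and ellipse axes of a binary mask
#'
#' The mask is summarized by the ellipse with the same second central
#' moments as the set of foreground pixel coordinates (in mm): axis lengths
#' are `4 * sqrt(eigenvalues)` of the coordinate covariance, which
#' reproduces `2a`/`2b` exactly for a filled continuous ellipse.
#'
#' @param mask Binary matrix.
#' @param spacing_mm Pixel spacing `c(row, col)` in mm.
#' @return List of class `mask_geometry` with `area_mm2`, `major_axis_mm`,
#'   `minor_axis_mm`, `centroid` (row, col, pixel units).
#' @export
mask_geometry <- function(mask, spacing_mm = c(1, 1)) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_input("mask is empty")
  spacing_mm <- unname(rep(spacing_mm, length.out = 2))
  area <- nrow(idx) * spacing_mm[1] * spacing_mm[2]
  coords <- cbind(idx[, 1] * spacing_mm[1], idx[, 2] * spacing_mm[2])
  centroid_px <- colMeans(idx)
  if (nrow(idx) == 1) {
    lam <- c(0, 0)
  } else {
    cv <- stats::cov(coords) * (nrow(idx) - 1) / nrow(idx) # population moments
    lam <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
  }
  structure(
    list(area_mm2 = area,
         major_axis_mm = 4 * sqrt(max(lam[1], 0)),
         minor_axis_mm = 4 * sqrt(max(lam[2], 0)),
         centroid = c(row = unname(centroid_px[1]), col = unname(centroid_px[2]))),
    class = "mask_geometry")
}

#' Morphological features of a multi-slice nodule
#'
#' `volume_mm3` approximates the nodule volume as the sum of slice areas
#' times the slice thickness; `max_major_diameter_mm` and `max_area_mm2` are
#' the maxima over member slices of the per-slice ellipse major axis and
#' area.
#'
#' @param masks List of binary slice masks (at least one nonempty).
#' @param spacing_mm Pixel spacing `c(row, col)` in mm.
#' @param thickness_mm Slice thickness in mm.
#' @return Named numeric vector `(volume_mm3, max_major_diameter_mm,
#'   max_area_mm2)`.
#' @export
lung_morph <- function(masks, spacing_mm, thickness_mm) {
  if (!length(masks) || all(vapply(masks, sum, numeric(1)) == 0)) {
    stop_input("need at least one nonempty mask")
  }
  if (is.na(thickness_mm) || thickness_mm <= 0) {
    stop_input("slice thickness is required for nodule volume")
  }
  geos <- lapply(masks[vapply(masks, sum, numeric(1)) > 0],
                 mask_geometry, spacing_mm = spacing_mm)
  areas <- vapply(geos, function(g) g$area_mm2, numeric(1))
  majors <- vapply(geos, function(g) g$major_axis_mm, numeric(1))
  c(volume_mm3 = sum(areas) * thickness_mm,
    max_major_diameter_mm = max(majors),
    max_area_mm2 = max(areas))
}

#' Morphological features of a single-slice (2-D) lesion
#'
#' @param mask Binary mask of the single slice.
#' @param spacing_mm Pixel spacing `c(row, col)` in mm.
#' @return Named numeric vector `(area_mm2, major_axis_mm)`.
#' @export
breast_morph <- function(mask, spacing_mm) {
  g <- mask_geometry(mask, spacing_mm)
  c(area_mm2 = g$area_mm2, major_axis_mm = g$major_axis_mm)
}

#' Morphological feature vector of a stored case
#'
#' Dispatches on slice count: single-slice cases get the 2-D lesion features
#' (area, major axis), multi-slice cases the nodule features (volume, max
#' major diameter, max area). Multi-slice cases require `thickness`.
#'
#' @param case A `synth_case` (or any list with `masks`, `spacing`,
#'   `thickness`).
#' @return Named numeric feature vector.
#' @export
morph_features <- function(case) {
  if (length(case$masks) == 1) {
    breast_morph(case$masks[[1]], case$spacing)
  } else {
    lung_morph(case$masks, case$spacing, case$thickness)
  }
}
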