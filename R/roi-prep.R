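## ROI preparation: crop around the mask, resize to the fixed 28x28 network
## input, and keep the original geometry as three auxiliary scalars (resize
## scale factors of both dimensions and the aspect ratio) so the network can
## recover what the resize discards.

PATCH_SIDE <- 28L

#' Crop the region of interest around a lesion mask
#'
#' Returns the axis-aligned bounding box of the mask, expanded on each side
#' by `ceiling(margin * extent)` pixels of that dimension and clipped to the
#' image bounds.
#'
#' @param image Grayscale matrix.
#' @param mask Binary matrix of the same shape.
#' @param margin Fractional margin per side (0 = tight box).
#' @return The cropped sub-matrix of `image`.
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' msk <- matrix(0, 64, 64); msk[11:20, 21:40] <- 1
#' dim(extract_roi(img, msk))          # 10 x 20
#' dim(extract_roi(img, msk, 0.1))     # 12 x 24
#' @export
extract_roi <- function(image, mask, margin = 0) {
  if (!all(dim(image) == dim(mask))) stop_input("image and mask shapes differ")
  if (sum(mask) == 0) stop_input("mask is empty")
  if (margin < 0) stop_input("margin must be nonnegative")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  er <- ceiling(margin * (rr[2] - rr[1] + 1))
  ec <- ceiling(margin * (cc[2] - cc[1] + 1))
  r0 <- max(1, rr[1] - er); r1 <- min(nrow(image), rr[2] + er)
  c0 <- max(1, cc[1] - ec); c1 <- min(ncol(image), cc[2] + ec)
  image[r0:r1, c0:c1, drop = FALSE]
}

## Bilinear resize with half-pixel center alignment: destination pixel i
## (0-based) samples source coordinate (i + 0.5) * in/out - 0.5, clamped.
## The identity mapping when in == out makes patch production idempotent.
bilinear_resize <- function(img, out_r, out_c) {
  in_r <- nrow(img); in_c <- ncol(img)
  src_of <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sr <- src_of(out_r, in_r)
  sc <- src_of(out_c, in_c)
  r0 <- pmin(floor(sr), in_r - 1); r1 <- pmin(r0 + 1, in_r - 1); fr <- sr - r0
  c0 <- pmin(floor(sc), in_c - 1); c1 <- pmin(c0 + 1, in_c - 1); fc <- sc - c0
  ## gather the four neighbours with 1-based indexing
  A <- img[r0 + 1, c0 + 1, drop = FALSE]
  B <- img[r0 + 1, c1 + 1, drop = FALSE]
  C <- img[r1 + 1, c0 + 1, drop = FALSE]
  D <- img[r1 + 1, c1 + 1, drop = FALSE]
  FR <- matrix(fr, out_r, out_c)
  FC <- matrix(fc, out_r, out_c, byrow = TRUE)
  A * (1 - FR) * (1 - FC) + B * (1 - FR) * FC + C * FR * (1 - FC) + D * FR * FC
}

#' Convert an ROI crop into a normalized 28x28 patch sample
#'
#' Bilinear-resizes the crop to 28x28 and min-max rescales intensities to
#' `[0, 1]` per patch (a constant crop maps to all zeros). The original
#' geometry is preserved as `scale_x = ncol/28`, `scale_y = nrow/28` and
#' `aspect_ratio = ncol/nrow` (width over height).
#'
#' @param roi Grayscale matrix, at least 2x2.
#' @param label `"benign"`, `"malignant"` or `"unknown"`.
#' @param case_id Case identifier carried through the pipeline.
#' @param slice_index 0-based slice position within the case.
#' @return An object of class `roi_sample`.
#' @examples
#' s <- to_patch(matrix(runif(56 * 84), 56, 84))
#' c(s$scale_y, s$scale_x, s$aspect_ratio) # 2, 3, 1.5
#' @export
to_patch <- function(roi, label = "unknown", case_id = NA_character_,
                     slice_index = 0L) {
  if (is.null(dim(roi)) || nrow(roi) < 2 || ncol(roi) < 2) {
    stop_input("roi must be at least 2x2")
  }
  if (!label %in% c("benign", "malignant", "unknown")) {
    stop_input("label must be benign, malignant or unknown")
  }
  patch <- minmax01(bilinear_resize(roi, PATCH_SIDE, PATCH_SIDE))
  structure(
    list(patch = patch,
         scale_x = ncol(roi) / PATCH_SIDE,
         scale_y = nrow(roi) / PATCH_SIDE,
         aspect_ratio = ncol(roi) / nrow(roi),
         label = label,
         case_id = case_id,
         slice_index = as.integer(slice_index)),
    class = "roi_sample")
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("roi_sample %s[%d] (%s): 28x28, scale %.2f x %.2f, aspect %.2f\n",
              x$case_id, x$slice_index, x$label, x$scale_y, x$scale_x,
              x$aspect_ratio))
  invisible(x)
}

aux_of <- function(s) c(scale_x = s$scale_x, scale_y = s$scale_y,
                        aspect_ratio = s$aspect_ratio)

#' Fit the auxiliary-input standardizer on a training set
#'
#' The three geometry scalars live on scales of roughly 1-20 and would
#' dominate sigmoid pre-activations if fed raw; they are z-scored with
#' training-set statistics only (a zero spread falls back to sd 1).
#'
#' @param samples List of `roi_sample` objects (the training folds only).
#' @return An object of class `aux_standardizer` with `$mean` and `$sd`.
#' @export
fit_aux_standardizer <- function(samples) {
  if (!length(samples)) stop_input("no samples to fit standardizer on")
  A <- t(vapply(samples, aux_of, numeric(3)))
  sd <- apply(A, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(mean = colMeans(A), sd = sd), class = "aux_standardizer")
}

#' Flatten a sample into the 787-length supervised input vector
#'
#' Row-major flattening of the 28x28 patch (784 values) followed by the
#' standardized auxiliary scalars `(scale_x, scale_y, aspect_ratio)`. During
#' unsupervised pretraining only the first 784 entries are consumed (see
#' [patch_vectors()]).
#'
#' @param s A `roi_sample`.
#' @param standardizer An [fit_aux_standardizer()] result; required.
#' @return Numeric vector of length 787.
#' @export
flatten_with_aux <- function(s, standardizer) {
  if (missing(standardizer) || !inherits(standardizer, "aux_standardizer")) {
    stop_input("a fitted aux_standardizer is required in supervised mode")
  }
  c(as.vector(t(s$patch)),
    unname((aux_of(s) - standardizer$mean) / standardizer$sd))
}

#' Stack patch pixels of many samples into a matrix for pretraining
#'
#' @param samples List of `roi_sample` objects.
#' @return A 784 x n matrix, one row-major flattened patch per column.
#' @export
patch_vectors <- function(samples) {
  vapply(samples, function(s) as.vector(t(s$patch)),
         numeric(PATCH_SIDE^2))
}
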