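## Seeded synthetic lesion/nodule image generator.
##
## Emulates the two kinds of inputs the CADx pipelines consume: 2-D
## ultrasound-like regions of interest (hypoechoic lesion on an echogenic
## background with multiplicative speckle and optional posterior shadowing)
## and CT-like nodule slice stacks (bright ellipsoidal nodule on dark lung
## parenchyma, sliced at a configurable thickness). Class signal is carried
## by boundary irregularity (a spiculation/lobulation proxy), internal
## texture contrast, size and orientation. Masks are produced exactly from
## the analytic boundary, standing in for manual outlines.

#' Configuration for the synthetic dataset generator
#'
#' Bundles and validates every knob of the generator. All randomness flows
#' from `seed`; the same configuration always produces byte-identical
#' datasets.
#'
#' @param modality `"us"` (single-slice ultrasound-like ROIs) or `"ct"`
#'   (multi-slice nodule stacks).
#' @param n_benign,n_malignant Number of cases per class (positive integers).
#' @param image_size Pixels per side of the square images.
#' @param pixel_spacing In-plane pixel size in mm.
#' @param slice_thickness Axial slice spacing in mm (CT only); must lie in
#'   (0, 10].
#' @param slices_per_case_range Integer interval `c(lo, hi)` from which the
#'   number of member slices of a CT case is drawn uniformly.
#' @param speckle_scale Multiplicative speckle strength in `[0, 1]` (US
#'   only): 0 is noise-free, 1 is fully developed Rayleigh speckle.
#' @param boundary_irregularity Named numeric `c(benign = , malignant = )`
#'   amplitude in `[0, 1]` of the star-convex boundary perturbation.
#' @param texture_contrast Named numeric `c(benign = , malignant = )`
#'   amplitude of the smooth internal texture field.
#' @param shadowing_prob Probability of posterior acoustic shadowing below a
#'   lesion (US only).
#' @param seed Integer seed driving all randomness.
#'
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config("us", n_benign = 5, n_malignant = 5, seed = 1)
#' @export
synth_config <- function(modality = c("us", "ct"),
                         n_benign,
                         n_malignant,
                         image_size = 64L,
                         pixel_spacing = if (match.arg(modality) == "us") 0.15 else 0.7,
                         slice_thickness = 2,
                         slices_per_case_range = c(3L, 9L),
                         speckle_scale = 0.6,
                         boundary_irregularity = c(benign = 0.05, malignant = 0.30),
                         texture_contrast = c(benign = 0.05, malignant = 0.25),
                         shadowing_prob = 0.25,
                         seed = 1L) {
  modality <- match.arg(modality)
  if (!is_count(n_benign) || !is_count(n_malignant)) {
    stop_input("n_benign and n_malignant must be positive integers")
  }
  if (!is_count(image_size) || image_size < 16) {
    stop_input("image_size must be an integer >= 16")
  }
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0) {
    stop_input("pixel_spacing must be positive (mm)")
  }
  if (modality == "ct" &&
      (!is.numeric(slice_thickness) || slice_thickness <= 0 || slice_thickness > 10)) {
    stop_input("slice_thickness must lie in (0, 10] mm")
  }
  if (modality == "ct") {
    r <- slices_per_case_range
    if (length(r) != 2 || !is_count(r[1]) || !is_count(r[2]) || r[1] > r[2]) {
      stop_input("slices_per_case_range must be an integer interval c(lo, hi), lo <= hi")
    }
  }
  if (!is_prob(speckle_scale)) stop_input("speckle_scale must lie in [0, 1]")
  for (nm in c("benign", "malignant")) {
    if (!is_prob(unname(boundary_irregularity[nm]))) {
      stop_input("boundary_irregularity must carry '", nm, "' in [0, 1]")
    }
    if (!is.finite(texture_contrast[nm]) || texture_contrast[nm] < 0) {
      stop_input("texture_contrast must carry nonnegative '", nm, "'")
    }
  }
  if (!is_prob(shadowing_prob)) stop_input("shadowing_prob must lie in [0, 1]")
  structure(
    list(modality = modality,
         n_benign = as.integer(n_benign),
         n_malignant = as.integer(n_malignant),
         image_size = as.integer(image_size),
         pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness,
         slices_per_case_range = as.integer(slices_per_case_range),
         speckle_scale = speckle_scale,
         boundary_irregularity = boundary_irregularity,
         texture_contrast = texture_contrast,
         shadowing_prob = shadowing_prob,
         seed = as.integer(seed)),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:", x$modality, "|", x$n_benign, "benign +",
      x$n_malignant, "malignant |", x$image_size, "px | seed", x$seed, "\n")
  invisible(x)
}

new_synth_case <- function(case_id, label, images, masks, spacing, thickness) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  structure(
    list(case_id = case_id, label = label, images = images, masks = masks,
         spacing = spacing, thickness = thickness),
    class = "synth_case")
}

#' @export
print.synth_case <- function(x, ...) {
  cat("synth_case", x$case_id, "(", x$label, "):", length(x$images),
      "slice(s),", nrow(x$images[[1]]), "x", ncol(x$images[[1]]), "px\n")
  invisible(x)
}

## Random boundary harmonics for a star-convex contour. The perturbation
## sum over k = 2..7 of c_k sin(k theta + phi_k) is standardized to unit RMS
## so `amplitude` is directly the RMS radial modulation.
draw_harmonics <- function(orders = 2:7) {
  coef <- stats::rnorm(length(orders)) / orders
  phase <- stats::runif(length(orders), 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = 256)
  s <- colSums(coef * sin(outer(orders, th) + phase))
  rms <- sqrt(mean(s^2))
  list(orders = orders, coef = if (rms > 0) coef / rms else coef, phase = phase)
}

## Binary mask of a star-convex region: pixel (r, c) is inside when its
## normalized elliptical radius does not exceed 1 + amplitude * harmonics.
## Star-convexity guarantees a single connected component.
star_mask <- function(nr, nc, center_rc, semi_axes_rc, amplitude = 0,
                      harmonics = NULL) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  v <- (rows - center_rc[1]) / semi_axes_rc[1]
  u <- (cols - center_rc[2]) / semi_axes_rc[2]
  rho <- sqrt(u^2 + v^2)
  if (amplitude > 0 && !is.null(harmonics)) {
    th <- atan2(v, u)
    mod <- matrix(0, nr, nc)
    for (i in seq_along(harmonics$orders)) {
      mod <- mod + harmonics$coef[i] *
        sin(harmonics$orders[i] * th + harmonics$phase[i])
    }
    bound <- pmax(1 + amplitude * mod, 0.3)
  } else {
    bound <- 1
  }
  (rho <= bound) * 1L
}

## Mean-one Rayleigh multiplier field for fully developed speckle.
rayleigh_unit <- function(n) {
  sqrt(-2 * log(stats::runif(n))) / sqrt(pi / 2)
}

synth_us_case <- function(cfg, label, case_id) {
  n <- cfg$image_size
  irr <- unname(cfg$boundary_irregularity[label])
  tex <- unname(cfg$texture_contrast[label])
  center <- n / 2 + stats::runif(2, -0.08 * n, 0.08 * n)
  ## size and orientation are drawn identically for both classes: the class
  ## signal is carried exclusively by the configured effect parameters
  ## (boundary irregularity and texture contrast)
  r0 <- stats::runif(1, 0.15 * n, 0.26 * n)
  aspect <- stats::runif(1, 0.7, 1.6)
  semi <- c(r0 / sqrt(aspect), r0 * sqrt(aspect)) # (row, col) semi-axes
  harm <- draw_harmonics()
  mask <- star_mask(n, n, center, semi, irr, harm)

  bg <- 0.55 + 0.04 * smooth_field(n, n) +
    0.08 * (matrix(seq_len(n), n, n) / n - 0.5) # mild depth gain
  lesion <- 0.22 + tex * 0.12 * smooth_field(n, n)
  envelope <- ifelse(mask > 0, lesion, bg)
  envelope <- pmin(pmax(envelope, 0.02), 1)

  if (stats::runif(1) < cfg$shadowing_prob) {
    cols <- matrix(rep(seq_len(n), each = n), n, n)
    rows <- matrix(seq_len(n), n, n)
    below <- rows > center[1] + semi[1] & abs(cols - center[2]) < 0.7 * semi[2]
    depth <- pmax(rows - (center[1] + semi[1]), 0) / n
    envelope <- ifelse(below, envelope * pmax(0.45, 1 - 2 * depth), envelope)
  }

  spk <- matrix(rayleigh_unit(n * n), n, n)
  img <- envelope * (1 + cfg$speckle_scale * (spk - 1))
  img <- pmax(img, 0)
  gain <- 30
  img <- log1p(gain * img) / log1p(gain)   # log compression, US display style
  new_synth_case(case_id, label, list(quantize8(img)), list(mask),
                 spacing = c(row = cfg$pixel_spacing, col = cfg$pixel_spacing),
                 thickness = NA_real_)
}

#' Generate a synthetic ultrasound-like dataset
#'
#' Each case is a single-slice square ROI containing one hypoechoic
#' star-convex lesion on an echogenic background, degraded by multiplicative
#' Rayleigh speckle and log-compressed to an 8-bit intensity grid. Malignant
#' cases are drawn with higher boundary irregularity and internal texture
#' contrast (and a taller-than-wide orientation) than benign ones; the exact
#' analytic boundary is returned as the mask.
#'
#' @param cfg A [synth_config()] with `modality = "us"`.
#' @return A list of `synth_case` objects (benign cases first).
#' @examples
#' cases <- generate_us_dataset(synth_config("us", 3, 3, seed = 7))
#' length(cases)
#' @export
generate_us_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$modality != "us") stop_input("cfg$modality must be 'us'")
  withr::with_seed(cfg$seed, {
    labels <- rep(c("benign", "malignant"), c(cfg$n_benign, cfg$n_malignant))
    lapply(seq_along(labels), function(i) {
      synth_us_case(cfg, labels[i], sprintf("us%04d", i))
    })
  })
}

## One nodule stack from explicit ellipsoid geometry. Slice j sits at
## z_j = (j - middle) * thickness so the middle slice cuts the equator; the
## in-plane cross-section at height z is the ellipse scaled by
## sqrt(1 - (z/az)^2), optionally lobulated by shared harmonics.
ellipsoid_stack_masks <- function(image_size, center_rc_px, semi_axes_mm,
                                  pixel_spacing, slice_thickness, n_slices,
                                  amplitude = 0, harmonics = NULL) {
  middle <- floor((n_slices - 1) / 2) + 1
  lapply(seq_len(n_slices), function(j) {
    z <- (j - middle) * slice_thickness
    s2 <- 1 - (z / semi_axes_mm[3])^2
    if (s2 <= 0) {
      matrix(0L, image_size, image_size)
    } else {
      s <- sqrt(s2)
      star_mask(image_size, image_size, center_rc_px,
                c(semi_axes_mm[1] * s / pixel_spacing,
                  semi_axes_mm[2] * s / pixel_spacing),
                amplitude, harmonics)
    }
  })
}

#' Build a single CT-like nodule case from explicit ellipsoid geometry
#'
#' Deterministic when `irregularity = 0`: masks are the analytic slice-plane
#' cross-sections of the ellipsoid, so their areas can be checked against
#' closed-form circle/ellipse formulas. Used internally by
#' [generate_ct_dataset()] and directly useful for geometric validation.
#'
#' @param semi_axes_mm Ellipsoid semi-axes in mm as `c(row, col, z)`.
#' @param n_slices Number of member slices; the middle slice (lower middle
#'   for even counts) cuts the equator.
#' @param slice_thickness Axial spacing in mm.
#' @param pixel_spacing In-plane pixel size in mm.
#' @param image_size Pixels per side.
#' @param irregularity Lobulation amplitude in `[0, 1]`.
#' @param harmonics Optional harmonics list from the generator's internal
#'   draw; `NULL` with positive `irregularity` draws fresh ones from the
#'   current RNG state.
#' @param label,case_id Metadata carried on the returned case.
#' @param texture_contrast Amplitude of the smooth internal texture field.
#' @param noise_sd Additive Gaussian noise level on the image.
#' @return A `synth_case` with one image and one exact mask per slice.
#' @examples
#' sphere <- ct_nodule_case(c(5, 5, 5), n_slices = 9, slice_thickness = 1)
#' vapply(sphere$masks, sum, numeric(1)) # symmetric, maximal in the middle
#' @export
ct_nodule_case <- function(semi_axes_mm, n_slices, slice_thickness,
                           pixel_spacing = 0.7, image_size = 64L,
                           irregularity = 0, harmonics = NULL,
                           label = "benign", case_id = "ct0001",
                           texture_contrast = 0, noise_sd = 0) {
  n <- image_size
  if (irregularity > 0 && is.null(harmonics)) harm <- draw_harmonics()
  else harm <- harmonics
  center <- c(n / 2, n / 2)
  masks <- ellipsoid_stack_masks(n, center, semi_axes_mm, pixel_spacing,
                                 slice_thickness, n_slices, irregularity, harm)
  if (any(vapply(masks, sum, numeric(1)) == 0)) {
    stop_input("ellipsoid too short for the requested slice grid: empty mask")
  }
  images <- lapply(masks, function(m) {
    bg <- 0.15 + 0.03 * if (noise_sd > 0) smooth_field(n, n) else 0
    nod <- 0.65 + texture_contrast * 0.12 *
      (if (texture_contrast > 0) smooth_field(n, n) else 0)
    img <- ifelse(m > 0, nod, bg)
    if (noise_sd > 0) img <- img + stats::rnorm(n * n, 0, noise_sd)
    quantize8(img)
  })
  new_synth_case(case_id, label, images, masks,
                 spacing = c(row = pixel_spacing, col = pixel_spacing),
                 thickness = slice_thickness)
}

synth_ct_case <- function(cfg, label, case_id) {
  irr <- unname(cfg$boundary_irregularity[label])
  tex <- unname(cfg$texture_contrast[label])
  rng <- cfg$slices_per_case_range
  k <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
  middle <- floor((k - 1) / 2) + 1
  ## z-extent must cover the farthest slice with margin so no mask is empty
  max_off <- max(middle - 1, k - middle)
  az <- cfg$slice_thickness * (max_off + stats::runif(1, 0.6, 1.2))
  ab <- if (label == "benign") stats::runif(2, 3, 7) else stats::runif(2, 5, 10)
  ## keep the nodule inside the field of view
  fov_half <- cfg$image_size * cfg$pixel_spacing / 2
  ab <- pmin(ab, 0.8 * fov_half)
  harm <- draw_harmonics()
  ct_nodule_case(c(ab[1], ab[2], az), k, cfg$slice_thickness,
                 cfg$pixel_spacing, cfg$image_size,
                 irregularity = irr, harmonics = harm,
                 label = label, case_id = case_id,
                 texture_contrast = tex, noise_sd = 0.05)
}

#' Generate a synthetic CT-like nodule dataset
#'
#' Each case is a stack of axial slices through one ellipsoidal nodule with
#' class-dependent size and lobulation; the per-slice mask is the exact
#' slice-plane cross-section of the (lobulated) ellipsoid, and the middle
#' slice carries the maximal cross-section. Malignant nodules are larger and
#' more lobulated, with stronger internal texture.
#'
#' @param cfg A [synth_config()] with `modality = "ct"`.
#' @return A list of `synth_case` objects (benign first).
#' @examples
#' cfg <- synth_config("ct", 2, 2, slices_per_case_range = c(3, 5), seed = 3)
#' cases <- generate_ct_dataset(cfg)
#' vapply(cases, function(x) length(x$images), integer(1))
#' @export
generate_ct_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$modality != "ct") stop_input("cfg$modality must be 'ct'")
  withr::with_seed(cfg$seed, {
    labels <- rep(c("benign", "malignant"), c(cfg$n_benign, cfg$n_malignant))
    lapply(seq_along(labels), function(i) {
      synth_ct_case(cfg, labels[i], sprintf("ct%04d", i))
    })
  })
}
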