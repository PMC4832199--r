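## Dataset layout on disk: 8-bit grayscale PNGs plus a manifest CSV with one
## row per slice. Paths in the manifest are relative to its own directory so
## a dataset directory can be moved wholesale.

#' Write a dataset of cases to disk with a manifest
#'
#' Images and masks are written as 8-bit grayscale PNG under `images/` and
#' `masks/`; the manifest CSV carries one row per slice with columns
#' `case_id`, `slice_index` (0-based), `label`, `image_path`, `mask_path`,
#' `pixel_spacing_mm`, `slice_thickness_mm`.
#'
#' @param cases List of `synth_case` objects (or any list with the same
#'   fields).
#' @param out_dir Output directory; created if absent.
#' @return The manifest path, invisibly usable by [read_manifest()].
#' @export
write_manifest <- function(cases, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory: ", out_dir)
  rows <- lapply(cases, function(cs) {
    stopifnot(cs$label %in% c("benign", "malignant"))
    n <- length(cs$images)
    img_rel <- sprintf("images/%s_s%02d.png", cs$case_id, seq_len(n) - 1)
    msk_rel <- sprintf("masks/%s_s%02d.png", cs$case_id, seq_len(n) - 1)
    for (j in seq_len(n)) {
      png::writePNG(cs$images[[j]], file.path(out_dir, img_rel[j]))
      png::writePNG(cs$masks[[j]] * 1.0, file.path(out_dir, msk_rel[j]))
    }
    data.frame(case_id = cs$case_id,
               slice_index = seq_len(n) - 1L,
               label = cs$label,
               image_path = img_rel,
               mask_path = msk_rel,
               pixel_spacing_mm = unname(cs$spacing["row"]),
               slice_thickness_mm = cs$thickness,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

#' Read a manifest back into a list of cases
#'
#' Inverse of [write_manifest()]: groups manifest rows by `case_id`
#' (slices ordered by `slice_index`) and loads images and masks.
#'
#' @param path Path to a manifest CSV.
#' @return A list of `synth_case` objects in first-appearance order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input("manifest not found: ", path)
  base <- dirname(path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "slice_index", "label", "image_path", "mask_path",
            "pixel_spacing_mm", "slice_thickness_mm")
  if (!all(need %in% names(m))) {
    stop_input("manifest lacks required columns: ",
               paste(setdiff(need, names(m)), collapse = ", "))
  }
  bad <- setdiff(unique(m$label), c("benign", "malignant"))
  if (length(bad)) stop_input("unknown labels in manifest: ", paste(bad, collapse = ", "))
  ids <- unique(m$case_id)
  lapply(ids, function(id) {
    rows <- m[m$case_id == id, , drop = FALSE]
    rows <- rows[order(rows$slice_index), , drop = FALSE]
    imgs <- lapply(file.path(base, rows$image_path), read_gray_png)
    msks <- lapply(file.path(base, rows$mask_path), function(p) {
      (read_gray_png(p) > 0.5) * 1L
    })
    sp <- rows$pixel_spacing_mm[1]
    new_synth_case(id, rows$label[1], imgs, msks,
                   spacing = c(row = sp, col = sp),
                   thickness = rows$slice_thickness_mm[1])
  })
}

## Grayscale PNG reader; collapses RGB(A) planes if present.
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}
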