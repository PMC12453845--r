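# Overlapping patch extraction.
#
# Each radiograph is resized so its long side equals the working resolution
# (default 1024), a dense grid of overlapping square candidate boxes is
# enumerated, every candidate is scored by the fraction of its pixels inside
# the lung-field mask, and the top-N candidates are kept. On a square image
# at the defaults (patch 256, overlap 25%) the grid has 5 x 5 = 25
# candidates, of which 11 are retained.

#' Patch extraction configuration
#'
#' @param n_patches Number of patches kept per image. The pipeline default
#'   is 11; 8 and 15 are the other studied settings.
#' @param overlap_ratio Fraction of the patch side shared by adjacent
#'   patches, in `[0, 1)`. Default 0.25.
#' @param patch_size Patch side length in working-resolution pixels.
#' @param working_resolution Long-side length the image is resized to before
#'   tiling, so patch pixel content needs no second resize.
#' @return A list of class `patch_config`.
#' @export
patch_config <- function(n_patches = 11L, overlap_ratio = 0.25,
                         patch_size = 256L, working_resolution = 1024L) {
  assert_that(n_patches >= 1, "n_patches must be >= 1")
  assert_that(overlap_ratio >= 0 && overlap_ratio < 1, "overlap_ratio must be in [0, 1)")
  assert_that(patch_size >= 8, "patch_size must be >= 8")
  assert_that(working_resolution >= patch_size,
              "working_resolution must be at least patch_size")
  structure(
    list(
      n_patches = as.integer(n_patches), overlap_ratio = overlap_ratio,
      patch_size = as.integer(patch_size),
      working_resolution = as.integer(working_resolution)
    ),
    class = "patch_config"
  )
}

# Anchor positions along one axis: 0, stride, 2*stride, ... with a final
# anchor clamped so the last patch ends exactly at the image edge.
#' @noRd
grid_anchors <- function(extent, patch_size, stride) {
  last <- extent - patch_size
  anchors <- seq(0L, last, by = stride)
  if (anchors[length(anchors)] != last) anchors <- c(anchors, last)
  as.integer(anchors)
}

#' Enumerate the candidate patch grid
#'
#' Boxes are half-open `[r0, r1) x [c0, c1)` in 0-based working-resolution
#' coordinates, returned in row-major order (row anchors outer, column
#' anchors inner). The stride is `round(patch_size * (1 - overlap_ratio))`;
#' the final anchor on each axis is clamped so the grid reaches the image
#' edge exactly.
#'
#' @param image_shape `c(rows, cols)` of the (resized) image.
#' @param patch_size Patch side length in pixels.
#' @param overlap_ratio Fraction of the patch side shared by neighbours.
#' @return A tibble with columns `r0`, `c0`, `r1`, `c1`.
#' @examples
#' candidate_grid(c(1024, 1024), 256, 0.25) # 25 boxes, stride 192
#' @export
candidate_grid <- function(image_shape, patch_size, overlap_ratio = 0.25) {
  assert_that(
    patch_size <= min(image_shape),
    sprintf(
      "patch_size %d exceeds image dimensions %d x %d",
      patch_size, image_shape[1], image_shape[2]
    ),
    "cxrcad_geometry_error"
  )
  stride <- max(1L, as.integer(round(patch_size * (1 - overlap_ratio))))
  r0 <- grid_anchors(image_shape[1], patch_size, stride)
  c0 <- grid_anchors(image_shape[2], patch_size, stride)
  grid <- tidyr::expand_grid(r0 = r0, c0 = c0) # row-major: r0 outer, c0 inner
  tibble::tibble(
    r0 = grid$r0, c0 = grid$c0,
    r1 = grid$r0 + as.integer(patch_size), c1 = grid$c0 + as.integer(patch_size)
  )
}

#' Lung fraction of a box
#'
#' Mean of the mask values inside a half-open, 0-based box.
#'
#' @param box Numeric vector or one-row data frame with `r0`, `c0`, `r1`,
#'   `c1`.
#' @param mask Binary matrix (1 = lung field).
#' @return Fraction of box pixels inside the lung field.
#' @export
lung_fraction <- function(box, mask) {
  b <- unlist(box[c("r0", "c0", "r1", "c1")])
  assert_that(
    b["r0"] >= 0 && b["c0"] >= 0 && b["r1"] <= nrow(mask) && b["c1"] <= ncol(mask),
    "box exceeds mask bounds"
  )
  mean(mask[(b["r0"] + 1):b["r1"], (b["c0"] + 1):b["c1"]])
}

# Resize an image and its mask so the long side equals `working_resolution`
# (aspect preserved; bilinear for intensities, nearest for the mask).
#' @noRd
to_working_resolution <- function(image, working_resolution) {
  d <- dim(image$pixels)
  scale <- working_resolution / max(d)
  shape <- as.integer(round(d * scale))
  shape[which.max(d)] <- as.integer(working_resolution)
  list(
    pixels = resize_bilinear(image$pixels, shape),
    mask = if (!is.null(image$mask)) resize_nearest(image$mask, shape) else NULL
  )
}

#' Extract the top lung-covering patches of a radiograph
#'
#' The image (and mask) are resized so the long side equals
#' `working_resolution`, the candidate grid is enumerated, each candidate is
#' scored by its lung fraction, and the `n_patches` highest-scoring
#' candidates are returned (ties broken by row-major grid order). Each patch
#' inherits the image's label. If the grid has fewer candidates than
#' `n_patches`, all are returned with a warning.
#'
#' @param image A [chest_image]; a lung mask is required (real or from the
#'   phantom generator).
#' @param config A [patch_config].
#' @return A tibble with one row per patch: `parent_id`, `r0`, `c0`, `r1`,
#'   `c1`, `lung_fraction`, `label`, and list-columns `pixels` and
#'   `mask` holding the patch crops.
#' @export
extract_patches <- function(image, config = patch_config()) {
  stopifnot(inherits(image, "chest_image"))
  if (is.null(image$mask)) {
    abort(
      paste0(
        "image '", image$id, "' has no lung mask; supply one (read_mask) or ",
        "use the phantom generator, which produces masks"
      ),
      class = "cxrcad_precondition_error"
    )
  }
  wk <- to_working_resolution(image, config$working_resolution)
  grid <- candidate_grid(dim(wk$pixels), config$patch_size, config$overlap_ratio)
  lf <- vapply(
    seq_len(nrow(grid)),
    function(i) lung_fraction(grid[i, ], wk$mask),
    numeric(1)
  )
  n <- config$n_patches
  if (nrow(grid) < n) {
    warn(sprintf(
      "only %d candidate patches available for '%s' (requested %d)",
      nrow(grid), image$id, n
    ))
    n <- nrow(grid)
  }
  keep <- order(-lf)[seq_len(n)] # order() is stable: ties stay row-major
  out <- grid[keep, ]
  out$lung_fraction <- lf[keep]
  crop <- function(m, b) m[(b[1] + 1):b[3], (b[2] + 1):b[4], drop = FALSE]
  out$pixels <- purrr::pmap(
    out[c("r0", "c0", "r1", "c1")],
    function(r0, c0, r1, c1) crop(wk$pixels, c(r0, c0, r1, c1))
  )
  out$mask <- purrr::pmap(
    out[c("r0", "c0", "r1", "c1")],
    function(r0, c0, r1, c1) crop(wk$mask, c(r0, c0, r1, c1))
  )
  tibble::tibble(
    parent_id = image$id,
    out[c("r0", "c0", "r1", "c1", "lung_fraction")],
    label = image$label,
    pixels = out$pixels,
    mask = out$mask
  )
}

#' Export patches to disk
#'
#' Writes each patch as `{parent_id}_{r0}_{c0}.png` plus a `patches.csv`
#' index (box, lung fraction, label, and any selection columns present).
#'
#' @param patches Patch tibble (optionally with selection stats appended).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patches <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(patches))) {
    png::writePNG(
      patches$pixels[[i]],
      file.path(dir, sprintf("%s_%d_%d.png", patches$parent_id[i],
                             patches$r0[i], patches$c0[i]))
    )
  }
  cols <- intersect(
    c("parent_id", "r0", "c0", "r1", "c1", "lung_fraction", "label",
      "t", "dof", "p", "decision", "dark_fraction"),
    names(patches)
  )
  readr::write_csv(patches[cols], file.path(dir, "patches.csv"))
  invisible(dir)
}

#' Extract patches for a whole cohort
#'
#' @param images A named list of [chest_image] objects (e.g. from
#'   [load_cohort()] or [generate_cohort_images()]).
#' @inheritParams extract_patches
#' @return One tibble with all patches, rows grouped by image in input
#'   order.
#' @export
extract_cohort_patches <- function(images, config = patch_config()) {
  dplyr::bind_rows(purrr::map(images, extract_patches, config = config))
}
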