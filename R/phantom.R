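# Synthetic phantom radiographs.
#
# The phantom emulates the gross intensity structure a patch-selection and
# classification pipeline relies on: two dark elliptical lung fields on a
# brighter mediastinum/soft-tissue background, periodic rib shading inside
# the lungs, an optional bright circular nodule of controlled contrast and
# radius (the "cancer" class), optional low-frequency background clutter,
# and additive Gaussian noise. The matching lung mask and label come for
# free, so every downstream stage is testable without clinical data.

#' Specify a phantom radiograph
#'
#' @param seed Integer seed; the phantom is a deterministic function of its
#'   spec.
#' @param size Image dimensions `c(rows, cols)` in pixels.
#' @param background_level Background (soft tissue / mediastinum) intensity.
#' @param lung_level Lung-field intensity; must be below `background_level`
#'   (lungs are radiolucent).
#' @param rib_amplitude Amplitude of the sinusoidal rib shading added inside
#'   the lung fields.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param with_nodule If `TRUE`, a bright disk is placed inside a lung field
#'   and the label becomes `"cancer"`.
#' @param nodule_contrast Intensity added inside the nodule disk.
#' @param nodule_radius Nodule radius in pixels (default scales with image
#'   size: 7% of the smaller dimension, a conspicuous 4-5 cm-equivalent
#'   nodule).
#' @param nodule_center Optional `c(row, col)` center (1-based). Must lie
#'   inside the lung mask; when `NULL` a center whose full disk fits inside
#'   a lung is drawn at random.
#' @param clutter_amplitude Amplitude of smooth low-frequency texture added
#'   outside the lung fields (soft-tissue variation, bowel gas, air outside
#'   the body); deep excursions produce dark non-lung pools. `0` disables
#'   it.
#' @param collimated If `TRUE`, the region outside a large body ellipse is
#'   rendered nearly black (exposed film beyond the patient), the way real
#'   radiographs carry dark corners and edge strips that are emphatically
#'   not lung.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         size = c(512L, 512L),
                         background_level = 0.55,
                         lung_level = 0.35,
                         rib_amplitude = 0.05,
                         noise_sigma = 0.02,
                         with_nodule = FALSE,
                         nodule_contrast = 0.30,
                         nodule_radius = NULL,
                         nodule_center = NULL,
                         clutter_amplitude = 0,
                         collimated = FALSE) {
  nodule_radius <- nodule_radius %||% max(4, round(0.07 * min(size)))
  assert_that(length(size) == 2 && all(size >= 32), "size must be at least 32 x 32")
  assert_that(lung_level < background_level,
              "lung_level must be below background_level (lungs are radiolucent)")
  assert_that(lung_level + nodule_contrast <= 1,
              "lung_level + nodule_contrast must not exceed 1")
  assert_that(noise_sigma >= 0, "noise_sigma must be non-negative")
  assert_that(!with_nodule || nodule_radius > 0,
              "nodule_radius must be positive when with_nodule")
  structure(
    list(
      seed = as.integer(seed), size = as.integer(size),
      background_level = background_level, lung_level = lung_level,
      rib_amplitude = rib_amplitude, noise_sigma = noise_sigma,
      with_nodule = isTRUE(with_nodule), nodule_contrast = nodule_contrast,
      nodule_radius = nodule_radius, nodule_center = nodule_center,
      clutter_amplitude = clutter_amplitude, collimated = isTRUE(collimated)
    ),
    class = "phantom_spec"
  )
}

# Union-of-two-ellipses lung mask. Geometry scales with image size; the two
# fields sit symmetrically about the midline and cover roughly a third of
# the frame, as lung fields do on a PA radiograph.
#' @noRd
lung_ellipses <- function(size) {
  h <- size[1]; w <- size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- function(cr, cc, a, b) {
    ((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1
  }
  left <- inside(0.52 * h, 0.30 * w, 0.33 * h, 0.16 * w)
  right <- inside(0.52 * h, 0.70 * w, 0.33 * h, 0.16 * w)
  (left | right) * 1
}

# Smooth low-frequency random field in [-1, 1]-ish range, built from a
# coarse Gaussian grid upsampled bilinearly. Consumes RNG.
#' @noRd
clutter_field <- function(size, cells = 8) {
  coarse <- matrix(rnorm(cells * cells), cells, cells)
  f <- resize_bilinear(coarse, size)
  f / max(abs(f))
}

#' Generate a phantom radiograph
#'
#' Deterministic in the spec: the same spec yields bit-identical pixels and
#' mask. Noise and nodule placement draw from independent streams derived
#' from `spec$seed`, so toggling `with_nodule` changes nothing outside the
#' nodule disk.
#'
#' @param spec A [phantom_spec].
#' @param id Image id (default derived from the seed).
#' @return A [chest_image] with mask and label (`"cancer"` iff
#'   `with_nodule`).
#' @examples
#' img <- generate_phantom(phantom_spec(seed = 7, with_nodule = TRUE))
#' img
#' @export
generate_phantom <- function(spec, id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  mask <- lung_ellipses(spec$size)

  pixels <- matrix(spec$background_level, h, w)
  pixels[mask == 1] <- spec$lung_level

  # Rib shading: periodic horizontal bands inside the lung fields (about
  # nine posterior rib shadows across the field height).
  if (spec$rib_amplitude != 0) {
    ribs <- matrix(sin(2 * pi * seq_len(h) / (h / 9)), h, w)
    pixels <- pixels + ribs * spec$rib_amplitude * (mask == 1)
  }

  # Collimation: outside a large body ellipse the film is almost black —
  # dark regions that are decidedly not lung.
  if (spec$collimated) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    body <- ((rows - 0.5 * h) / (0.72 * h))^2 +
      ((cols - 0.5 * w) / (0.46 * w))^2 <= 1
    pixels[!body] <- 0.12
  }

  # Off-lung clutter: smooth low-frequency texture outside the lung fields
  # (soft-tissue variation, bowel gas, air outside the body). Deep negative
  # excursions create dark non-lung pools, the structures that defeat
  # mask-free dark-pixel selection on real radiographs.
  if (spec$clutter_amplitude != 0) {
    f <- with_seed(derive_seed(spec$seed, 3L), clutter_field(c(h, w)))
    pixels <- pixels + spec$clutter_amplitude * f * (mask == 0)
  }

  if (spec$with_nodule) {
    r <- spec$nodule_radius
    center <- spec$nodule_center
    if (is.null(center)) {
      center <- with_seed(derive_seed(spec$seed, 2L), {
        # sample lung pixels until the full disk fits inside the mask
        ok <- which(mask == 1, arr.ind = TRUE)
        ok <- ok[ok[, 1] > r & ok[, 1] <= h - r & ok[, 2] > r & ok[, 2] <= w - r, , drop = FALSE]
        idx <- sample.int(nrow(ok))
        found <- NULL
        for (i in idx) {
          cr <- ok[i, 1]; cc <- ok[i, 2]
          rr <- (cr - r):(cr + r); cc2 <- (cc - r):(cc + r)
          disk <- outer(rr - cr, cc2 - cc, function(a, b) a^2 + b^2 <= r^2)
          if (all(mask[rr, cc2][disk] == 1)) { found <- c(cr, cc); break }
        }
        assert_that(!is.null(found), "no lung position can contain the nodule disk")
        found
      })
    } else if (mask[center[1], center[2]] != 1) {
      abort("nodule_center lies outside the lung field", class = "cxrcad_placement_error")
    }
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    disk <- (rows - center[1])^2 + (cols - center[2])^2 <= r^2
    pixels <- pixels + spec$nodule_contrast * disk
    attr(mask, "nodule_center") <- center
  }

  if (spec$noise_sigma > 0) {
    noise <- with_seed(derive_seed(spec$seed, 1L), matrix(rnorm(h * w, 0, spec$noise_sigma), h, w))
    pixels <- pixels + noise
  }

  img <- chest_image(
    clip01(pixels),
    id = id %||% sprintf("phantom_%08d", spec$seed),
    mask = matrix(as.double(mask), h, w),
    label = if (spec$with_nodule) "cancer" else "normal"
  )
  if (spec$with_nodule) attr(img, "nodule_center") <- attr(mask, "nodule_center")
  img
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_cancer` nodule phantoms and `n_normal` normal phantoms as PNG
#' image/mask pairs plus a `manifest.csv`, all deterministically derived
#' from `seed` (per-image seeds are hashed from the cohort seed and index).
#'
#' @param n_cancer,n_normal Number of images per class.
#' @param seed Cohort seed.
#' @param out_dir Output directory (created if needed).
#' @param spec Base [phantom_spec] whose appearance parameters
#'   (levels, noise, contrast, clutter) apply to every image; `seed`,
#'   `with_nodule` and `nodule_center` are overridden per image.
#' @return The manifest tibble (also written to `out_dir/manifest.csv`).
#' @export
generate_cohort <- function(n_cancer, n_normal, seed, out_dir,
                            spec = phantom_spec()) {
  assert_that(n_cancer >= 0 && n_normal >= 0, "counts must be non-negative")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory %s", out_dir), class = "cxrcad_io_error")
  }
  labels <- c(rep("cancer", n_cancer), rep("normal", n_normal))
  records <- purrr::imap(labels, function(lab, i) {
    sp <- spec
    sp$seed <- derive_seed(seed, i)
    sp$with_nodule <- lab == "cancer"
    sp$nodule_center <- NULL
    id <- sprintf("phantom_%03d_%s", i, lab)
    img <- generate_phantom(sp, id = id)
    img_file <- paste0(id, ".png")
    mask_file <- paste0(id, "_mask.png")
    png::writePNG(img$pixels, file.path(out_dir, img_file))
    png::writePNG(img$mask, file.path(out_dir, mask_file))
    tibble::tibble(id = id, image = img_file, mask = mask_file, label = lab)
  })
  manifest <- dplyr::bind_rows(records)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  out <- manifest
  out$image <- file.path(out_dir, out$image)
  out$mask <- file.path(out_dir, out$mask)
  class(out) <- c("cxr_manifest", class(out))
  out
}

#' Generate a phantom cohort in memory
#'
#' Same contract as [generate_cohort()] but returns the images directly
#' without touching the filesystem — convenient for simulation studies and
#' tests.
#'
#' @inheritParams generate_cohort
#' @return A named list of [chest_image] objects.
#' @export
generate_cohort_images <- function(n_cancer, n_normal, seed,
                                   spec = phantom_spec()) {
  labels <- c(rep("cancer", n_cancer), rep("normal", n_normal))
  imgs <- purrr::imap(labels, function(lab, i) {
    sp <- spec
    sp$seed <- derive_seed(seed, i)
    sp$with_nodule <- lab == "cancer"
    sp$nodule_center <- NULL
    generate_phantom(sp, id = sprintf("phantom_%03d_%s", i, lab))
  })
  setNames(imgs, purrr::map_chr(imgs, "id"))
}

#' Display a chest image
#'
#' @param object A [chest_image].
#' @param show_mask If `TRUE`, outlines the lung field.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chest_image <- function(object, show_mask = TRUE, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$pixels)),
    col = seq_len(ncol(object$pixels))
  )
  df$intensity <- as.vector(t(object$pixels))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s)", object$id, object$label)) +
    ggplot2::theme_void()
  if (show_mask && !is.null(object$mask)) {
    df$lung <- as.vector(t(object$mask))
    p <- p + ggplot2::geom_contour(
      data = df, ggplot2::aes(z = .data$lung), breaks = 0.5,
      colour = "red", linewidth = 0.3
    )
  }
  p
}
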