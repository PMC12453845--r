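# Radiograph, mask and manifest I/O.
#
# Radiographs travel through the pipeline as `chest_image` records: a numeric
# intensity matrix in [0, 1] (row-major semantics, origin top-left), an
# optional binary lung-field mask of identical shape, a diagnostic label and
# an id. All box coordinates in the package are 0-based and half-open,
# [r0, r1) x [c0, c1).

#' Construct a chest radiograph record
#'
#' Bundles an intensity matrix with its optional lung-field mask, label and
#' id. This is the unit every pipeline stage consumes.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`, origin top-left.
#' @param id Non-empty string identifying the image.
#' @param mask Optional binary matrix (0 = background, 1 = lung field) with
#'   the same dimensions as `pixels`.
#' @param label One of `"cancer"`, `"normal"`, `"unknown"`
#'   (case-insensitive).
#' @return An object of class `chest_image`: a list with elements `id`,
#'   `pixels`, `mask` (or `NULL`) and `label`.
#' @examples
#' img <- chest_image(matrix(runif(16), 4), id = "toy")
#' img
#' @export
chest_image <- function(pixels, id, mask = NULL, label = "unknown") {
  assert_that(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  assert_that(
    all(is.finite(pixels)) && min(pixels) >= 0 && max(pixels) <= 1,
    "pixel intensities must lie in [0, 1]"
  )
  assert_that(is.character(id) && length(id) == 1 && nzchar(id), "id must be a non-empty string")
  if (!is.null(mask)) {
    assert_that(
      is.matrix(mask) && identical(dim(mask), dim(pixels)),
      "mask must match the pixel dimensions"
    )
    assert_that(all(mask %in% c(0, 1)), "mask values must be 0 or 1")
    storage.mode(mask) <- "double"
  }
  structure(
    list(id = id, pixels = pixels, mask = mask, label = canonical_label(label)),
    class = "chest_image"
  )
}

#' @export
print.chest_image <- function(x, ...) {
  cat(
    sprintf(
      "<chest_image '%s'> %d x %d, label = %s, mask = %s\n",
      x$id, nrow(x$pixels), ncol(x$pixels), x$label,
      if (is.null(x$mask)) "absent" else sprintf("%.1f%% lung", 100 * mean(x$mask))
    )
  )
  invisible(x)
}

#' Read a headerless 16-bit big-endian radiograph
#'
#' Decodes the raw raster dialect used by the JSRT digital image database:
#' headerless, unsigned 16-bit big-endian samples in row-major order with a
#' 12-bit dynamic range (0-4095). Intensities are divided by 4095 and clipped
#' to `[0, 1]`.
#'
#' @param path File to read.
#' @param width,height Raster dimensions in pixels (JSRT ships 2048 x 2048).
#' @param invert If `TRUE`, samples are inverted (`4095 - value`) before
#'   normalisation, for copies stored with an inverted lookup table.
#' @param id Image id; defaults to the file name without extension.
#' @return A [chest_image] with label `"unknown"` and no mask.
#' @seealso [write_jsrt_raw()] for the inverse operation.
#' @export
read_jsrt_raw <- function(path, width = 2048, height = 2048, invert = FALSE,
                          id = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path), "cxrcad_io_error")
  expected <- as.double(width) * height * 2
  actual <- file.size(path)
  if (!isTRUE(actual == expected)) {
    abort(
      sprintf(
        "raw raster size mismatch for %s: expected %.0f bytes (%d x %d x 2), found %.0f",
        path, expected, width, height, actual
      ),
      class = "cxrcad_format_error"
    )
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "integer", n = width * height, size = 2,
                  signed = FALSE, endian = "big")
  if (isTRUE(invert)) vals <- 4095 - vals
  pixels <- matrix(clip01(vals / 4095), nrow = height, ncol = width, byrow = TRUE)
  chest_image(pixels, id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a radiograph as headerless 16-bit big-endian raw
#'
#' Quantises intensities to the 12-bit range (`round(pixels * 4095)`) and
#' writes unsigned 16-bit big-endian samples in row-major order, the format
#' [read_jsrt_raw()] decodes.
#'
#' @param image A [chest_image] (or bare numeric matrix in `[0, 1]`).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_jsrt_raw <- function(image, path) {
  pixels <- if (inherits(image, "chest_image")) image$pixels else image
  assert_that(
    is.matrix(pixels) && min(pixels) >= 0 && max(pixels) <= 1,
    "image pixels must lie in [0, 1]"
  )
  vals <- as.integer(round(t(pixels) * 4095))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort(sprintf("cannot open %s for writing: %s", path, conditionMessage(e)),
          class = "cxrcad_io_error")
  })
  on.exit(close(con))
  writeBin(vals, con, size = 2, endian = "big")
  invisible(path)
}

# Decode a PNG or TIFF file to a numeric array scaled to [0, 1].
#' @noRd
read_raster <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path), "cxrcad_io_error")
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    abort(sprintf("unsupported raster format '.%s' (expected PNG or TIFF): %s", ext, path),
          class = "cxrcad_format_error")
  }
}

#' Read a grayscale radiograph from PNG or TIFF
#'
#' Both decoders rescale samples by the format's maximum value (255 for
#' 8-bit, 65535 for 16-bit), so intensities arrive in `[0, 1]`. Colour
#' images are converted to luminance (Rec. 709 weights); an alpha channel is
#' dropped.
#'
#' @inheritParams read_jsrt_raw
#' @return A [chest_image] with label `"unknown"` and no mask.
#' @export
read_image <- function(path, id = NULL) {
  arr <- read_raster(path)
  pixels <- if (length(dim(arr)) == 2) {
    arr
  } else if (dim(arr)[3] >= 3) {
    0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  } else {
    arr[, , 1]
  }
  chest_image(clip01(pixels), id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Read a binary lung-field mask
#'
#' Any nonzero sample is treated as lung. If the raster's dimensions differ
#' from `shape`, it is resampled by nearest neighbour, provided the aspect
#' ratio matches within 1%.
#'
#' @param path PNG or TIFF mask file (single-channel; extra channels are
#'   reduced by maximum).
#' @param shape Target dimensions `c(rows, cols)`; defaults to the raster's
#'   own.
#' @return A 0/1 numeric matrix of dimension `shape`.
#' @export
read_mask <- function(path, shape = NULL) {
  arr <- read_raster(path)
  m <- if (length(dim(arr)) == 2) arr else apply(arr, c(1, 2), max)
  m[m != 0] <- 1
  if (!is.null(shape) && !identical(dim(m), as.integer(shape))) {
    ar_in <- nrow(m) / ncol(m)
    ar_out <- shape[1] / shape[2]
    if (abs(ar_in - ar_out) / ar_out > 0.01) {
      abort(
        sprintf(
          "mask aspect ratio %.4f does not match requested %.4f (beyond 1%%)",
          ar_in, ar_out
        ),
        class = "cxrcad_shape_error"
      )
    }
    m <- resize_nearest(m, shape)
  }
  if (all(m == 0)) warn("mask is entirely empty (no lung field)")
  m
}

#' Load a dataset manifest
#'
#' The manifest is a CSV with header columns `id,image,mask,label` (`mask`
#' optional) mapping image ids to file paths and diagnostic labels. Relative
#' paths are resolved against the manifest's directory. Labels are folded to
#' lowercase and must be `cancer` or `normal`.
#'
#' @param path Manifest CSV file.
#' @return A tibble of class `cxr_manifest` with columns `id`, `image`,
#'   `mask` (`NA` when absent) and `label`.
#' @examples
#' \dontrun{
#' manifest <- load_manifest("jsrt/manifest.csv")
#' dplyr::count(manifest, label)
#' }
#' @export
load_manifest <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path), "cxrcad_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(
    all(c("id", "image", "label") %in% names(df)),
    "manifest must have columns id, image, label (mask optional)",
    "cxrcad_validation_error"
  )
  if (!"mask" %in% names(df)) df$mask <- NA_character_
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate manifest ids: %s", paste(unique(dup), collapse = ", ")),
          class = "cxrcad_validation_error")
  }
  df$label <- canonical_label(df$label)
  if (any(df$label == "unknown")) {
    abort("manifest labels must be 'cancer' or 'normal'", class = "cxrcad_validation_error")
  }
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  out <- tibble::tibble(
    id = as.character(df$id),
    image = resolve(df$image),
    mask = resolve(ifelse(is.na(df$mask) | df$mask == "", NA_character_, df$mask)),
    label = df$label
  )
  class(out) <- c("cxr_manifest", class(out))
  out
}

#' Per-label counts of a manifest
#'
#' @param manifest A manifest tibble from [load_manifest()] or
#'   [generate_cohort()].
#' @return A tibble with columns `label` and `n`.
#' @export
manifest_counts <- function(manifest) {
  dplyr::count(tibble::as_tibble(manifest), .data$label, name = "n")
}

#' Load every image (and mask) referenced by a manifest
#'
#' @inheritParams manifest_counts
#' @return A named list of [chest_image] objects keyed by id.
#' @export
load_cohort <- function(manifest) {
  purrr::pmap(
    list(manifest$id, manifest$image, manifest$mask, manifest$label),
    function(id, image, mask, label) {
      img <- if (grepl("\\.(img|raw)$", image, ignore.case = TRUE)) {
        read_jsrt_raw(image, id = id)
      } else {
        read_image(image, id = id)
      }
      m <- if (!is.na(mask)) read_mask(mask, shape = dim(img$pixels)) else NULL
      chest_image(img$pixels, id = id, mask = m, label = label)
    }
  ) |> setNames(manifest$id)
}
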