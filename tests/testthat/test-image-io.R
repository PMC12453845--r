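test_that("raw 16-bit big-endian round trip preserves quantised intensities", {
  img <- tiny_phantom(seed = 2, size = c(64, 64))
  path <- withr::local_tempfile(fileext = ".img")
  write_jsrt_raw(img, path)
  expect_equal(file.size(path), 64 * 64 * 2)
  back <- read_jsrt_raw(path, width = 64, height = 64)
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 4095 + 1e-12)
  # decoding is monotone: pixel ordering preserved
  ord <- order(img$pixels)
  expect_true(all(diff(back$pixels[ord]) > -1e-12))
})

test_that("raw encoding quantises exactly as round(pixels * 4095), big-endian", {
  img <- chest_image(matrix(c(0, 0.5, 1, 0.25), 2, 2, byrow = TRUE), id = "q")
  path <- withr::local_tempfile(fileext = ".img")
  write_jsrt_raw(img, path)
  bytes <- readBin(path, "raw", n = 8)
  # row-major order: 0, 0.5, 1, 0.25 -> 0, 2048, 4095, 1024
  vals <- as.integer(bytes[c(1, 3, 5, 7)]) * 256L + as.integer(bytes[c(2, 4, 6, 8)])
  expect_identical(vals, c(0L, 2048L, 4095L, 1024L))
})

test_that("raw reader rejects files whose size does not match", {
  path <- withr::local_tempfile(fileext = ".img")
  writeBin(raw(100), path)
  expect_error(read_jsrt_raw(path, 2048, 2048), class = "cxrcad_format_error")
  expect_error(read_jsrt_raw(path, 2048, 2048), "8,?388,?608|8388608")
})

test_that("raw reader applies the inversion flag before normalisation", {
  img <- chest_image(matrix(c(0, 1, 0.5, 0.25), 2, 2), id = "inv")
  path <- withr::local_tempfile(fileext = ".img")
  write_jsrt_raw(img, path)
  inv <- read_jsrt_raw(path, 2, 2, invert = TRUE)
  expect_equal(inv$pixels, 1 - img$pixels, tolerance = 1e-3)
})

test_that("PNG intensities are rescaled by the format maximum", {
  p0 <- withr::local_tempfile(fileext = ".png")
  p1 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 8, 8), p0)
  png::writePNG(matrix(1, 8, 8), p1)
  expect_true(all(read_image(p0)$pixels == 0))
  expect_true(all(read_image(p1)$pixels == 1))
})

test_that("16-bit rasters rescale by 65535", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(32768 / 65535, 4, 4), path, bits.per.sample = 16L)
  img <- read_image(path)
  expect_equal(img$pixels[1, 1], 32768 / 65535, tolerance = 1e-9)
})

test_that("masks binarise any nonzero value and resample by nearest neighbour", {
  path <- withr::local_tempfile(fileext = ".png")
  m <- matrix(0, 16, 16)
  m[5:12, 3:9] <- 1
  png::writePNG(m * 200 / 255, path)
  mk <- read_mask(path)
  expect_true(all(mk %in% c(0, 1)))
  expect_equal(mk, m)
  # 2x upsampling replicates each pixel 2x2
  up <- read_mask(path, shape = c(32, 32))
  expect_equal(up, m[rep(1:16, each = 2), rep(1:16, each = 2)])
})

test_that("empty masks warn and incompatible aspect ratios error", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 8, 8), path)
  expect_warning(read_mask(path), "empty")
  p2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 8, 16), p2)
  expect_error(read_mask(p2, shape = c(32, 32)), class = "cxrcad_shape_error")
})

test_that("manifests load with per-label counts, case-folded labels", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "manifest.csv")
  writeLines(c("id,image,mask,label",
               "a,a.png,a_m.png,cancer",
               "b,b.png,b_m.png,Cancer",
               "c,c.png,,normal"), csv)
  mf <- load_manifest(csv)
  expect_s3_class(mf, "cxr_manifest")
  counts <- manifest_counts(mf)
  expect_equal(counts$n[counts$label == "cancer"], 2L)
  expect_equal(counts$n[counts$label == "normal"], 1L)
  expect_equal(sum(counts$n), nrow(mf))
  expect_true(is.na(mf$mask[3]))
  # relative paths resolve against the manifest directory
  expect_equal(mf$image[1], file.path(dir, "a.png"))
})

test_that("manifests reject duplicate ids and unknown labels", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,image,label", "a,x.png,cancer", "a,y.png,normal"), csv)
  expect_error(load_manifest(csv), class = "cxrcad_validation_error")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,image,label", "a,x.png,malignant"), csv2)
  expect_error(load_manifest(csv2), "malignant")
})
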