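test_that("candidate grid follows the stride arithmetic with a clamped last anchor", {
  g <- candidate_grid(c(1024, 1024), 256, 0.25)
  expect_equal(nrow(g), 25)
  anchors <- sort(unique(g$r0))
  expect_equal(anchors, c(0, 192, 384, 576, 768))
  expect_true(all(g$r1 <= 1024 & g$c1 <= 1024))
  # non-square image: final anchor clamped to the edge
  g2 <- candidate_grid(c(512, 1024), 256, 0.25)
  expect_equal(sort(unique(g2$r0)), c(0, 192, 256))
  expect_equal(nrow(g2), 15)
  # degenerate single tile
  g3 <- candidate_grid(c(256, 256), 256, 0.25)
  expect_equal(nrow(g3), 1)
  expect_equal(unlist(g3[1, ]), c(r0 = 0, c0 = 0, r1 = 256, c1 = 256))
  expect_error(candidate_grid(c(128, 128), 256), class = "cxrcad_geometry_error")
})

test_that("adjacent patches share round(patch_size * overlap) pixels per axis", {
  g <- candidate_grid(c(1024, 1024), 256, 0.25)
  r0 <- sort(unique(g$r0))
  interior <- diff(r0)[1:3] # clamped final anchor excluded
  expect_true(all(256 - interior == round(256 * 0.25)))
  # union of candidates covers the full working-resolution image
  covered <- matrix(FALSE, 64, 64) # 16x downsampled coverage map
  for (i in seq_len(nrow(g))) {
    covered[(g$r0[i] / 16 + 1):(g$r1[i] / 16), (g$c0[i] / 16 + 1):(g$c1[i] / 16)] <- TRUE
  }
  expect_true(all(covered))
})

test_that("lung fraction is the mean mask value inside a half-open box", {
  mask <- matrix(0, 100, 100)
  mask[, 51:100] <- 1 # right half is lung
  expect_equal(lung_fraction(c(r0 = 0, c0 = 60, r1 = 10, c1 = 70), mask), 1)
  expect_equal(lung_fraction(c(r0 = 0, c0 = 0, r1 = 10, c1 = 10), mask), 0)
  # box centred on the mask edge: exactly half its pixels are lung
  expect_equal(lung_fraction(c(r0 = 10, c0 = 40, r1 = 30, c1 = 60), mask), 0.5)
  expect_error(lung_fraction(c(r0 = 0, c0 = 0, r1 = 101, c1 = 10), mask))
})

test_that("extract_patches equals a brute-force top-N lung-fraction ranking", {
  img <- generate_phantom(phantom_spec(seed = 21))
  cfg <- patch_config(n_patches = 11)
  got <- extract_patches(img, cfg)
  expect_equal(nrow(got), 11)

  # independent oracle: score the full grid, sort stably, take the top 11
  wk_scale <- cfg$working_resolution / max(dim(img$mask))
  mask_wk <- img$mask[
    pmin(pmax(floor((seq_len(1024) - 0.5) / wk_scale) + 1, 1), 512),
    pmin(pmax(floor((seq_len(1024) - 0.5) / wk_scale) + 1, 1), 512)
  ]
  grid <- candidate_grid(c(1024, 1024), cfg$patch_size, cfg$overlap_ratio)
  lf <- vapply(seq_len(nrow(grid)), function(i) {
    mean(mask_wk[(grid$r0[i] + 1):grid$r1[i], (grid$c0[i] + 1):grid$c1[i]])
  }, numeric(1))
  top <- grid[order(-lf)[1:11], ]
  expect_equal(got[c("r0", "c0", "r1", "c1")], top, ignore_attr = TRUE)
  expect_equal(got$lung_fraction, sort(lf, decreasing = TRUE)[1:11])
  expect_true(all(got$lung_fraction > 0))
  expect_true(all(got$label == img$label))
})

test_that("selection is monotone in n_patches and ties break row-major", {
  img <- generate_phantom(phantom_spec(seed = 22))
  p8 <- extract_patches(img, patch_config(n_patches = 8))
  p11 <- extract_patches(img, patch_config(n_patches = 11))
  key <- function(p) paste(p$r0, p$c0)
  expect_true(all(key(p8) %in% key(p11)))

  # empty mask: every candidate ties at 0, first n in row-major order win
  img$mask[] <- 0
  pe <- extract_patches(img, patch_config(n_patches = 3))
  expect_equal(pe$lung_fraction, c(0, 0, 0))
  grid <- candidate_grid(c(1024, 1024), 256, 0.25)
  expect_equal(pe[c("r0", "c0")], grid[1:3, c("r0", "c0")], ignore_attr = TRUE)
})

test_that("patch extraction demands a lung mask and warns on short grids", {
  img <- generate_phantom(phantom_spec(seed = 1))
  img$mask <- NULL
  expect_error(extract_patches(img), class = "cxrcad_precondition_error")
  img2 <- generate_phantom(phantom_spec(seed = 1))
  expect_warning(
    out <- extract_patches(img2, patch_config(n_patches = 30)),
    "30"
  )
  expect_equal(nrow(out), 25)
})

test_that("patch pixel content matches its box crop at working resolution", {
  img <- generate_phantom(phantom_spec(seed = 8, size = c(256L, 256L)))
  cfg <- patch_config(n_patches = 2, patch_size = 128, working_resolution = 256)
  p <- extract_patches(img, cfg)
  expect_equal(dim(p$pixels[[1]]), c(128, 128))
  expect_equal(
    p$pixels[[1]],
    img$pixels[(p$r0[1] + 1):p$r1[1], (p$c0[1] + 1):p$c1[1]]
  )
  expect_equal(p$lung_fraction[1], mean(p$mask[[1]]))
})
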