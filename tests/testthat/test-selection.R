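test_that("two-sample t matches the reference implementation on random data", {
  withr::with_seed(42, {
    for (i in 1:40) {
      n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
      g1 <- rnorm(n1, sd = runif(1, 0.5, 2))
      g2 <- rnorm(n2, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
      for (fl in c("welch", "pooled")) {
        ours <- two_sample_t(g1, g2, fl)
        ref <- stats::t.test(g1, g2, var.equal = fl == "pooled")
        expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(ours$dof, unname(ref$parameter), tolerance = 1e-12)
        expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("the worked example gives t = -2, dof = 8, two-sided p ~ 0.0805", {
  res <- two_sample_t(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
  expect_equal(res$t, -2)
  expect_equal(res$dof, 8)
  expect_equal(res$p, 2 * pt(-2, 8), tolerance = 1e-12)
  expect_equal(res$p, 0.0805, tolerance = 1e-3)
})

test_that("degenerate zero-variance inputs follow the sentinel rules", {
  eq <- two_sample_t(rep(0.4, 3), rep(0.4, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  ne <- two_sample_t(rep(0.2, 50), rep(0.8, 50))
  expect_true(is.infinite(ne$t) && ne$t < 0)
  expect_equal(ne$p, 0)
  expect_error(two_sample_t(1, 1:5), class = "cxrcad_insufficient_data_error")
})

test_that("welch equals pooled for equal sizes and equal variances; p is symmetric", {
  g1 <- c(1, 2, 3, 4)
  g2 <- c(2, 3, 4, 5) # same sample variance, same n
  expect_equal(two_sample_t(g1, g2, "welch")$t, two_sample_t(g1, g2, "pooled")$t)
  expect_equal(two_sample_t(g1, g2, "welch")$dof, two_sample_t(g1, g2, "pooled")$dof)
  withr::with_seed(7, {
    a <- rnorm(20); b <- rnorm(25, 1)
    expect_equal(two_sample_t(a, b)$p, two_sample_t(b, a)$p)
    expect_equal(two_sample_t(a, b)$t, -two_sample_t(b, a)$t)
  })
})

test_that("patch scoring applies the boundary rules and the p threshold", {
  px <- matrix(runif(64^2), 64)
  all_bg <- matrix(0, 64, 64)
  expect_equal(score_patch(px, all_bg)$decision, "forced_discard")
  expect_equal(score_patch(px, all_bg + 1)$decision, "forced_retain")
  # boundary patch from a separable phantom: huge contrast, p << 0.003
  img <- generate_phantom(phantom_spec(seed = 31, noise_sigma = 0.02))
  p <- extract_patches(img, patch_config(n_patches = 25))
  straddle <- which(p$lung_fraction > 0.3 & p$lung_fraction < 0.7)[1]
  st <- score_patch(p$pixels[[straddle]], p$mask[[straddle]])
  expect_lt(st$p, 1e-10)
  expect_equal(st$decision, "retain")
  # the same stats re-derived with the bare test (oracle equivalence)
  ref <- two_sample_t(p$pixels[[straddle]][p$mask[[straddle]] == 1],
                      p$pixels[[straddle]][p$mask[[straddle]] == 0])
  expect_equal(st$t, ref$t)
  expect_equal(st$p, ref$p)
  expect_equal(st$n_lung + st$n_nonlung, 256^2)
})

test_that("under the null the retention rate of tested patches is ~ alpha", {
  # lung and non-lung intensities drawn from one distribution: the tested
  # patches should be rejected at about the 0.003 threshold
  n_patches <- 2000
  reject <- withr::with_seed(314, {
    vapply(seq_len(n_patches), function(i) {
      px <- matrix(0.5 + rnorm(32 * 32, 0, 0.02), 32)
      mask <- matrix(0, 32, 32)
      mask[, 1:16] <- 1
      score_patch(px, mask)$decision == "retain"
    }, logical(1))
  })
  expect_equal(mean(reject), 0.003, tolerance = 0.004)
})

test_that("raising the p threshold never shrinks the retained set", {
  img <- generate_phantom(phantom_spec(seed = 33, noise_sigma = 0.1,
                                       rib_amplitude = 0.15))
  p <- extract_patches(img, patch_config(n_patches = 25))
  kept <- lapply(c(1e-6, 0.003, 0.5), function(th) {
    sel <- select_patches(p, selection_config(p_threshold = th), quiet = TRUE)
    paste(sel$retained$r0, sel$retained$c0)
  })
  expect_true(all(kept[[1]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[3]]))
})

test_that("select_patches returns per-patch stats consistent with re-testing", {
  img <- generate_phantom(phantom_spec(seed = 34))
  p <- extract_patches(img, patch_config(n_patches = 11))
  sel <- select_patches(p, quiet = TRUE)
  expect_equal(nrow(sel$stats), 11)
  redo <- vapply(seq_len(11), function(i) {
    score_patch(p$pixels[[i]], p$mask[[i]])$decision
  }, character(1))
  expect_equal(sel$stats$decision, redo)
  expect_equal(sel$retained$r0,
               sel$stats$r0[sel$stats$decision %in% c("retain", "forced_retain")])
  # empty input passes through
  empty <- select_patches(p[0, ], quiet = TRUE)
  expect_equal(nrow(empty$retained), 0)
})

test_that("Otsu thresholding splits bimodal patches and drops flat ones", {
  bimodal <- matrix(rep(c(0.2, 0.8), each = 512), 32)
  th <- otsu_threshold(bimodal)
  expect_gt(th, 0.2)
  expect_lte(th, 0.8)
  patches <- tibble::tibble(
    parent_id = c("a", "b", "c"),
    pixels = list(matrix(0.9, 32, 32), bimodal, matrix(0.05, 32, 32) + 0)
  )
  w <- capture_warnings(kept <- threshold_select(patches))
  expect_length(w, 2) # one per constant patch
  expect_match(w, "constant", all = TRUE)
  # bright constant and dark constant are discarded (Otsu undefined);
  # the bimodal patch has dark fraction 0.5 >= 0.3 and is retained
  expect_equal(kept$parent_id, "b")
  expect_equal(kept$dark_fraction, 0.5)
  # empty input is fine
  expect_equal(nrow(threshold_select(patches[0, ])), 0)
  # fixed cutoff variant
  kept2 <- threshold_select(patches, dark_cutoff = 0.5, min_dark_fraction = 0.3)
  expect_equal(sort(kept2$parent_id), c("b", "c"))
})

test_that("Otsu's threshold maximises between-class variance (brute-force oracle)", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- matrix(c(rnorm(300, 0.3, 0.05), rnorm(724, 0.7, 0.05)), 32)
      x <- pmin(pmax(x, 0), 1)
      v <- as.vector(x)
      cands <- seq(1 / 512, 1 - 1 / 512, by = 1 / 512)
      bc <- vapply(cands, function(t) {
        w0 <- mean(v < t)
        if (w0 == 0 || w0 == 1) return(0)
        w0 * (1 - w0) * (mean(v[v < t]) - mean(v[v >= t]))^2
      }, numeric(1))
      expect_equal(otsu_threshold(x), cands[which.max(bc)], tolerance = 2 / 256)
    }
  })
})
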