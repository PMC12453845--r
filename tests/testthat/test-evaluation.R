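test_that("confusion counts cover the exhaustive four-case enumeration", {
  cm <- confusion(c("cancer", "cancer", "normal", "normal"),
                  c("cancer", "normal", "cancer", "normal"))
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L), ignore_attr = TRUE)
  perfect <- confusion(rep(c("cancer", "normal"), 5), rep(c("cancer", "normal"), 5))
  expect_equal(perfect$fp + perfect$fn, 0)
  worst <- confusion(rep("cancer", 7), rep("normal", 7))
  expect_equal(worst$tp, 0)
  expect_equal(worst$fn, 7)
  expect_error(confusion("cancer", c("cancer", "normal")),
               class = "cxrcad_validation_error")
})

test_that("metrics reproduce the worked arithmetic and the perfect case", {
  m <- compute_metrics(list(tp = 80, fn = 20, tn = 70, fp = 30))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$specificity, 0.70)
  expect_equal(m$precision, 80 / 110)
  expect_equal(m$f1, 2 * (80 / 110) * 0.8 / (80 / 110 + 0.8))
  expect_false(m$degenerate)
  p <- compute_metrics(list(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(p[1:5]), rep(1, 5), ignore_attr = TRUE)
})

test_that("metrics match independent formula evaluation on random matrices", {
  for (cm in random_confusions(300, seed = 3)) {
    m <- compute_metrics(cm)
    with(cm, {
      expect_equal(m$accuracy, (tp + tn) / (tp + tn + fp + fn))
      if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      # accuracy decomposes over class prevalences
      if (tp + fn > 0 && tn + fp > 0) {
        expect_equal(
          m$accuracy,
          (m$sensitivity * (tp + fn) + m$specificity * (tn + fp)) /
            (tp + tn + fp + fn)
        )
      }
      # F1 is bounded by precision and sensitivity
      if (tp + fp > 0 && tp + fn > 0 && m$precision + m$sensitivity > 0) {
        expect_gte(m$f1, min(m$precision, m$sensitivity) - 1e-12)
        expect_lte(m$f1, max(m$precision, m$sensitivity) + 1e-12)
      }
    })
  }
})

test_that("degenerate denominators yield flagged zero sentinels, not errors", {
  m <- compute_metrics(list(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_true(m$degenerate)
  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)))
})

test_that("grouped stratified folds partition ids with balanced classes", {
  manifest <- tibble::tibble(
    id = sprintf("img%03d", 1:247),
    label = rep(c("cancer", "normal"), c(154, 93))
  )
  folds <- grouped_stratified_kfold(manifest, k = 10, seed = 4)
  sizes <- table(folds$fold)
  expect_true(all(sizes %in% c(24, 25)))
  expect_equal(sum(sizes), 247)
  # each id appears exactly once
  expect_setequal(folds$id, manifest$id)
  expect_false(any(duplicated(folds$id)))
  # stratification: per-fold class counts within 1 of proportionality
  per <- table(folds$fold, folds$label)
  expect_true(all(abs(per[, "cancer"] - 15.4) <= 1))
  expect_true(all(abs(per[, "normal"] - 9.3) <= 1))
  # train/val splits complement each other
  for (sp in fold_splits(folds)) {
    expect_length(intersect(sp$train, sp$val), 0)
    expect_setequal(c(sp$train, sp$val), manifest$id)
  }
  # determinism
  expect_identical(folds, grouped_stratified_kfold(manifest, k = 10, seed = 4))
  expect_false(identical(folds$fold,
                         grouped_stratified_kfold(manifest, 10, seed = 5)$fold))
  expect_error(grouped_stratified_kfold(manifest[1:5, ], k = 10),
               class = "cxrcad_validation_error")
})

test_that("minimal k = 2 cross-validation on 4 images produces 2 folds of 2", {
  manifest <- tibble::tibble(id = letters[1:4],
                             label = c("cancer", "cancer", "normal", "normal"))
  folds <- grouped_stratified_kfold(manifest, k = 2, seed = 1)
  expect_equal(unname(table(folds$fold)), c(2L, 2L), ignore_attr = TRUE)
  per <- table(folds$fold, folds$label)
  expect_true(all(per == 1))
})

test_that("image aggregation follows the mean and majority rules", {
  one <- aggregate_image(0.9)
  expect_equal(one$probability, 0.9)
  expect_equal(one$label, "cancer")
  mean_rule <- aggregate_image(c(0.4, 0.45, 0.8))
  expect_equal(mean_rule$probability, 0.55)
  expect_equal(mean_rule$label, "cancer")
  expect_equal(aggregate_image(c(0.5, 0.5))$label, "cancer") # tie to positive
  expect_equal(aggregate_image(c(0.1, 0.2, 0.3))$label, "normal")
  expect_equal(aggregate_image(c(0.9, 0.1, 0.1), rule = "majority")$label, "normal")
  expect_equal(aggregate_image(c(0.9, 0.1), rule = "majority")$label, "cancer")
  expect_error(aggregate_image(numeric(0)), class = "cxrcad_aggregation_error")
})
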