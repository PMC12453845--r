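# Independent parameter-count oracle: conv k^2*c_in*c_out + c_out,
# batch-norm 2*c, dense in*out + out; computed from the config alone.
count_custom_params <- function(input_size, filters, fusion = 128, classes = 2) {
  c_in <- c(1, filters[-5])
  conv <- sum(4 * c_in * filters + filters)
  bn <- sum(2 * filters)
  side <- input_size / 2^5 / 2 # five stride-2 blocks then 2x2 pooling
  flat <- side^2 * filters[5]
  dense <- flat * fusion + fusion + fusion * classes + classes
  conv + bn + dense
}

test_that("the custom CNN has the documented 16-layer sequence and shapes", {
  m <- build_custom_cnn(model_config())
  expect_equal(m$counted_layers, 16)
  tb <- tidy(m)
  expect_equal(tb$type,
               c(rep(c("conv", "bn", "dropout"), 5),
                 "avgpool", "flatten", "dense", "dense", "softmax"))
  # spatial sizes halve through the blocks: 128, 64, 32, 16, 8, then 4
  conv_shapes <- tb$output_shape[tb$type == "conv"]
  expect_equal(conv_shapes,
               c("128x128x32", "64x64x64", "32x32x96", "16x16x128", "8x8x160"))
  expect_equal(tb$output_shape[tb$type == "avgpool"], "4x4x160")
  expect_equal(tb$output_shape[tb$type == "flatten"], "2560")
})

test_that("total parameters equal the arithmetic oracle for several configs", {
  for (cfg in list(
    model_config(),
    model_config(input_size = 64, block_filters = c(8, 16, 16, 16, 16)),
    model_config(input_size = 128, block_filters = c(16, 32, 48, 64, 80),
                 fusion_units = 128)
  )) {
    m <- build_custom_cnn(cfg)
    expect_equal(
      m$n_parameters,
      count_custom_params(cfg$input_size, cfg$block_filters, cfg$fusion_units,
                          cfg$n_classes)
    )
    expect_equal(sum(tidy(m)$parameters), m$n_parameters)
  }
})

test_that("softmax outputs are probability rows for any input", {
  m <- build_custom_cnn(reduced_model_config())
  pr <- predict(m, list(matrix(0, 64, 64), matrix(1, 64, 64),
                        matrix(runif(64^2), 64)))
  expect_equal(pr$p_normal + pr$p_cancer, rep(1, 3), tolerance = 1e-6)
  expect_true(all(pr$p_normal >= 0 & pr$p_cancer >= 0))
})

test_that("indivisible input sizes are rejected with the failing stage named", {
  expect_error(build_custom_cnn(model_config(input_size = 100)),
               class = "cxrcad_shape_error")
  expect_error(build_custom_cnn(model_config(input_size = 100)), "block")
})

test_that("baseline builders produce the standard architectures", {
  a <- build_baseline("alexnet", input_size = 64)
  expect_equal(a$counted_layers, 8)
  expect_equal(sum(tidy(a)$type == "conv"), 5)
  expect_equal(sum(tidy(a)$type == "dense"), 3)
  r <- build_baseline("resnet34", input_size = 64)
  expect_equal(r$counted_layers, 34)
  g <- build_baseline("googlenet", input_size = 64)
  expect_equal(g$counted_layers, 22)
  for (m in list(a, r, g)) {
    pr <- predict(m, list(matrix(0, 64, 64)))
    expect_equal(pr$p_normal + pr$p_cancer, 1, tolerance = 1e-6)
  }
  expect_error(build_baseline("vgg16"), class = "cxrcad_option_error")
  expect_error(build_baseline("vgg16"), "alexnet")
})

test_that("dropout is inactive at inference: repeated passes agree", {
  m <- build_custom_cnn(reduced_model_config())
  x <- list(matrix(runif(64^2), 64))
  expect_identical(predict(m, x), predict(m, x))
})

test_that("batch norm uses batch statistics in training, running statistics at inference", {
  ns <- asNamespace("cxrcad")
  m <- build_custom_cnn(reduced_model_config(), init_seed = 2)
  # a strongly skewed batch: batch statistics differ from the (fresh)
  # running statistics, so train and eval forwards must differ
  x <- array(0.9, c(1, 64, 64, 4)) # channels-first batch
  tr <- ns$nn_seq_forward(m$layers, m$params, m$state, x, training = TRUE,
                          dropout_active = FALSE)
  ev <- ns$nn_seq_forward(m$layers, m$params, m$state, x, training = FALSE)
  expect_gt(max(abs(tr$out - ev$out)), 1e-6)
  # training mode updated the running statistics
  expect_false(identical(tr$state, m$state))
})

test_that("checkpoints round-trip weights, statistics and predictions", {
  toy <- tibble::tibble(
    pixels = c(replicate(3, matrix(0.1, 64, 64), simplify = FALSE),
               replicate(3, matrix(0.9, 64, 64), simplify = FALSE)),
    label = rep(c("normal", "cancer"), each = 3)
  )
  m <- train_classifier(build_custom_cnn(reduced_model_config()), toy,
                        train_config(epochs = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_equal(predict(back, toy), predict(m, toy), tolerance = 1e-12)
  expect_true(back$trained)
})
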