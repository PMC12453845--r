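# Model zoo: the custom five-block CNN and standard baseline builders.

#' Configuration of the custom five-block CNN
#'
#' The classifier stacks five blocks of Conv2D (2 x 2 kernel, ReLU) +
#' batch normalisation + dropout, followed by non-overlapping average
#' pooling, flatten, a fully connected fusion layer, the class head and
#' softmax. Stride-2 convolutions halve the spatial extent in every block,
#' taking a 256 x 256 patch down to 8 x 8 before pooling.
#'
#' @param input_size Side length of the (square, single-channel) input.
#'   Must be divisible by 64 so the extent halves cleanly through the five
#'   conv blocks and the pooling layer.
#' @param block_filters Channel widths of the five blocks.
#' @param kernel Convolution kernel size; the architecture is defined with
#'   2 x 2 kernels.
#' @param block_stride Convolution stride within each block (2 downsamples).
#' @param dropout_rate Dropout rate in every block.
#' @param pooling `"average"` (2 x 2 non-overlapping, the architecture's
#'   choice) or `"global_average"`.
#' @param fusion_units Width of the fully connected fusion layer between
#'   flatten and the class head.
#' @param n_classes Number of output classes.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_size = 256L, block_filters = c(32L, 64L, 96L, 128L, 160L),
                         kernel = 2L, block_stride = 2L, dropout_rate = 0.5,
                         pooling = c("average", "global_average"),
                         fusion_units = 128L, n_classes = 2L) {
  assert_that(length(block_filters) == 5, "block_filters must have 5 entries")
  assert_that(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate must be in [0, 1)")
  assert_that(kernel == 2L, "the architecture is defined with a 2 x 2 kernel")
  structure(
    list(
      input_size = as.integer(input_size),
      block_filters = as.integer(block_filters),
      kernel = as.integer(kernel), block_stride = as.integer(block_stride),
      dropout_rate = dropout_rate, pooling = match.arg(pooling),
      fusion_units = as.integer(fusion_units), n_classes = as.integer(n_classes)
    ),
    class = "model_config"
  )
}

# Wrap an initialised layer stack into a cnn_model object.
#' @noRd
new_cnn_model <- function(layers, input_size, n_classes, config, arch,
                          counted_layers, init_seed) {
  init <- with_seed(init_seed, nn_init(layers, c(input_size, input_size, 1L)))
  table <- dplyr::bind_rows(init$table)
  structure(
    list(
      arch = arch, layers = layers, params = init$params, state = init$state,
      config = config, input_size = as.integer(input_size),
      n_classes = as.integer(n_classes), layer_table = table,
      n_parameters = sum(table$parameters), counted_layers = counted_layers,
      init_seed = as.integer(init_seed), trained = FALSE, history = NULL
    ),
    class = "cnn_model"
  )
}

#' Build the custom five-block CNN
#'
#' Layer sequence: five blocks of `Conv2D(2x2, stride 2, ReLU) -> BatchNorm
#' -> Dropout`, then 2 x 2 non-overlapping average pooling, flatten, a
#' fully connected fusion layer (ReLU), the class head, and softmax. By the
#' architecture's counting convention the network has 16 layers: 5 conv +
#' 5 batch-norm + 5 dropout + the class head (pooling, flatten, the fusion
#' merge and softmax are not counted).
#'
#' @param config A [model_config].
#' @param init_seed Seed for the (He-normal) weight initialisation;
#'   [train_classifier()] re-initialises from its own seed.
#' @return A `cnn_model`: layer table, parameter registry, running
#'   statistics, and metadata (`n_parameters`, `counted_layers`). Use
#'   [predict.cnn_model()] for class probabilities, [tidy()] for the layer
#'   table.
#' @examples
#' model <- build_custom_cnn(model_config(input_size = 64))
#' model
#' @export
build_custom_cnn <- function(config = model_config(), init_seed = 1L) {
  s <- config$input_size
  chain <- s
  for (b in 1:5) {
    if (chain %% config$block_stride != 0) {
      abort(
        sprintf(
          "input_size %d does not divide cleanly at block %d (extent %d, stride %d)",
          s, b, chain, config$block_stride
        ),
        class = "cxrcad_shape_error"
      )
    }
    chain <- chain %/% config$block_stride
  }
  if (config$pooling == "average" && chain %% 2 != 0) {
    abort(
      sprintf("input_size %d leaves extent %d at the pooling layer (needs 2 x 2)",
              s, chain),
      class = "cxrcad_shape_error"
    )
  }
  layers <- list()
  for (b in 1:5) {
    layers <- c(layers, list(
      nn_conv(sprintf("conv%d", b), config$block_filters[b],
              kernel = config$kernel, stride = config$block_stride,
              edge_pad = TRUE),
      nn_bn(sprintf("bn%d", b)),
      nn_dropout(sprintf("drop%d", b), config$dropout_rate)
    ))
  }
  layers <- c(
    layers,
    list(if (config$pooling == "average") nn_avgpool(2L) else nn_gap()),
    list(
      nn_flatten(),
      nn_dense("fusion", config$fusion_units, activation = "relu"),
      nn_dense("fc", config$n_classes),
      nn_softmax()
    )
  )
  new_cnn_model(layers, s, config$n_classes, config, arch = "custom",
                counted_layers = 5L + 5L + 5L + 1L, init_seed = init_seed)
}

# Basic 3x3 residual block pair of ResNet-34.
#' @noRd
resnet_block <- function(name, c_out, downsample) {
  body <- list(
    nn_conv(paste0(name, "_conv1"), c_out, kernel = 3L,
            stride = if (downsample) 2L else 1L, pad = 1L, activation = "linear"),
    nn_bn(paste0(name, "_bn1")),
    nn_relu(),
    nn_conv(paste0(name, "_conv2"), c_out, kernel = 3L, pad = 1L,
            activation = "linear"),
    nn_bn(paste0(name, "_bn2"))
  )
  shortcut <- if (downsample) {
    list(
      nn_conv(paste0(name, "_proj"), c_out, kernel = 1L, stride = 2L,
              activation = "linear", projection = TRUE),
      nn_bn(paste0(name, "_projbn"))
    )
  } else {
    NULL
  }
  nn_residual(name, body, shortcut)
}

# GoogLeNet inception module; cfg = c(b1, b2_reduce, b2, b3_reduce, b3, b4).
#' @noRd
inception_module <- function(name, cfg) {
  nn_inception(name, list(
    list(nn_conv(paste0(name, "_1x1"), cfg[1], kernel = 1L)),
    list(
      nn_conv(paste0(name, "_3x3r"), cfg[2], kernel = 1L),
      nn_conv(paste0(name, "_3x3"), cfg[3], kernel = 3L, pad = 1L)
    ),
    list(
      nn_conv(paste0(name, "_5x5r"), cfg[4], kernel = 1L),
      nn_conv(paste0(name, "_5x5"), cfg[5], kernel = 5L, pad = 2L)
    ),
    list(
      nn_maxpool(3L, 1L, pad = 1L),
      nn_conv(paste0(name, "_pool"), cfg[6], kernel = 1L)
    )
  ))
}

#' Build a standard baseline classifier
#'
#' The published AlexNet, GoogLeNet or ResNet-34 architecture, adapted only
#' at the boundaries: the first convolution takes one input channel and the
#' final classifier emits `n_classes`. Local response normalisation
#' (AlexNet) and the auxiliary classifiers (GoogLeNet) are omitted, as is
#' now conventional. The predict contract is identical to the custom CNN's.
#'
#' @param name One of `"alexnet"`, `"googlenet"`, `"resnet34"`.
#' @param input_size Input side length in pixels.
#' @param n_classes Number of output classes.
#' @param init_seed Seed for weight initialisation.
#' @return A `cnn_model`. `counted_layers` follows each architecture's
#'   standard depth convention (8 / 22 / 34 weighted layers).
#' @export
build_baseline <- function(name, input_size = 64L, n_classes = 2L, init_seed = 1L) {
  valid <- c("alexnet", "googlenet", "resnet34")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    abort(
      sprintf("unknown architecture '%s'; valid names: %s",
              paste(name, collapse = ","), paste(valid, collapse = ", ")),
      class = "cxrcad_option_error"
    )
  }
  layers <- switch(name,
    alexnet = list(
      nn_conv("conv1", 64L, kernel = 11L, stride = 4L, pad = 2L),
      nn_maxpool(3L, 2L),
      nn_conv("conv2", 192L, kernel = 5L, pad = 2L),
      nn_maxpool(3L, 2L),
      nn_conv("conv3", 384L, kernel = 3L, pad = 1L),
      nn_conv("conv4", 256L, kernel = 3L, pad = 1L),
      nn_conv("conv5", 256L, kernel = 3L, pad = 1L),
      nn_maxpool(3L, 2L),
      nn_flatten(),
      nn_dropout("drop6", 0.5),
      nn_dense("fc6", 4096L, activation = "relu"),
      nn_dropout("drop7", 0.5),
      nn_dense("fc7", 4096L, activation = "relu"),
      nn_dense("fc8", n_classes),
      nn_softmax()
    ),
    googlenet = c(
      list(
        nn_conv("conv1", 64L, kernel = 7L, stride = 2L, pad = 3L),
        nn_maxpool(3L, 2L, pad = 1L),
        nn_conv("conv2r", 64L, kernel = 1L),
        nn_conv("conv2", 192L, kernel = 3L, pad = 1L),
        nn_maxpool(3L, 2L, pad = 1L)
      ),
      list(
        inception_module("i3a", c(64, 96, 128, 16, 32, 32)),
        inception_module("i3b", c(128, 128, 192, 32, 96, 64)),
        nn_maxpool(3L, 2L, pad = 1L),
        inception_module("i4a", c(192, 96, 208, 16, 48, 64)),
        inception_module("i4b", c(160, 112, 224, 24, 64, 64)),
        inception_module("i4c", c(128, 128, 256, 24, 64, 64)),
        inception_module("i4d", c(112, 144, 288, 32, 64, 64)),
        inception_module("i4e", c(256, 160, 320, 32, 128, 128)),
        nn_maxpool(3L, 2L, pad = 1L),
        inception_module("i5a", c(256, 160, 320, 32, 128, 128)),
        inception_module("i5b", c(384, 192, 384, 48, 128, 128)),
        nn_gap(),
        nn_flatten(),
        nn_dropout("drop", 0.4),
        nn_dense("fc", n_classes),
        nn_softmax()
      )
    ),
    resnet34 = {
      blocks <- list(
        nn_conv("conv1", 64L, kernel = 7L, stride = 2L, pad = 3L,
                activation = "linear"),
        nn_bn("bn1"),
        nn_relu(),
        nn_maxpool(3L, 2L, pad = 1L)
      )
      plan <- list(c(3L, 64L), c(4L, 128L), c(6L, 256L), c(3L, 512L))
      for (st in seq_along(plan)) {
        for (bl in seq_len(plan[[st]][1])) {
          blocks <- c(blocks, list(resnet_block(
            sprintf("l%db%d", st, bl), plan[[st]][2],
            downsample = st > 1 && bl == 1
          )))
        }
      }
      c(blocks, list(nn_gap(), nn_flatten(), nn_dense("fc", n_classes),
                     nn_softmax()))
    }
  )
  counted <- switch(name,
    alexnet = 8L, # 5 conv + 3 FC
    googlenet = 22L, # depth along the longest weighted path
    resnet34 = count_weighted_layers(layers) # 33 conv + 1 FC
  )
  new_cnn_model(layers, input_size, n_classes,
                config = list(input_size = as.integer(input_size),
                              n_classes = as.integer(n_classes)),
                arch = name, counted_layers = counted, init_seed = init_seed)
}

# Weighted-layer depth: conv and dense layers on the main path (projection
# shortcuts excluded, as in the standard counting convention).
#' @noRd
count_weighted_layers <- function(layers) {
  total <- 0L
  for (layer in layers) {
    total <- total + switch(layer$type,
      conv = if (isTRUE(layer$projection)) 0L else 1L,
      dense = 1L,
      residual = count_weighted_layers(layer$body),
      inception = max(vapply(layer$branches, count_weighted_layers, integer(1))),
      0L
    )
  }
  total
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model '%s'> input %d x %d x 1, %d classes, %s parameters (%d counted layers)%s\n",
    x$arch, x$input_size, x$input_size, x$n_classes,
    format(x$n_parameters, big.mark = ","), x$counted_layers,
    if (x$trained) ", trained" else ""
  ))
  print(x$layer_table, n = min(nrow(x$layer_table), 20))
  invisible(x)
}

#' @describeIn build_custom_cnn Layer table of a model: one row per layer
#'   with name, type, output shape and parameter count.
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @export
tidy.cnn_model <- function(x, ...) x$layer_table

#' @describeIn build_custom_cnn One-row model summary (architecture,
#'   parameter count, counted layers, training status).
#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(
    arch = x$arch, input_size = x$input_size, n_classes = x$n_classes,
    n_parameters = x$n_parameters, counted_layers = x$counted_layers,
    trained = x$trained
  )
}

# Stack a list of patch matrices (resized to the model input) into the
# channels-first (1, H, W, N) batch array the engine consumes.
#' @noRd
patches_to_batch <- function(pixel_list, input_size) {
  n <- length(pixel_list)
  x <- array(0, c(1L, input_size, input_size, n))
  for (i in seq_len(n)) {
    x[1L, , , i] <- resize_bilinear(pixel_list[[i]], c(input_size, input_size))
  }
  x
}

#' Predict class probabilities for patches
#'
#' Runs the network in inference mode (dropout inactive, batch norm using
#' running statistics). Patches are resized bilinearly to the model's input
#' size.
#'
#' @param object A `cnn_model`.
#' @param patches Patch tibble with a `pixels` list-column (or a bare list
#'   of matrices).
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return A tibble with one row per patch: `p_normal`, `p_cancer`,
#'   `pred_label`, plus `parent_id` and `label` when present in `patches`.
#' @export
predict.cnn_model <- function(object, patches, batch_size = 64L, ...) {
  pixel_list <- if (is.data.frame(patches)) patches$pixels else patches
  n <- length(pixel_list)
  probs <- matrix(0, n, object$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- patches_to_batch(pixel_list[idx], object$input_size)
    out <- nn_seq_forward(object$layers, object$params, object$state, x,
                          training = FALSE)
    probs[idx, ] <- t(out$out)
  }
  res <- tibble::tibble(
    p_normal = probs[, 1],
    p_cancer = probs[, 2],
    pred_label = ifelse(probs[, 2] >= 0.5, "cancer", "normal")
  )
  if (is.data.frame(patches)) {
    if ("parent_id" %in% names(patches)) res <- dplyr::bind_cols(
      patches["parent_id"], res
    )
    if ("label" %in% names(patches)) res$label <- patches$label
  }
  res
}
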