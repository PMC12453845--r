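# Training loop: softmax cross-entropy, Adam, deterministic under a seed.

#' Training hyper-parameters
#'
#' @param epochs Number of passes over the training patches. The headline
#'   configuration trains for 100 epochs; 50/70/90/100 sweeps are the
#'   studied settings.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @param seed Seed controlling weight initialisation, shuffling and
#'   dropout; a run is deterministic given (seed, data order).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8, seed = 1L) {
  assert_that(epochs >= 1, "epochs must be >= 1")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, seed = as.integer(seed)),
    class = "train_config"
  )
}

# One-hot targets: column 1 = normal, column 2 = cancer (positive class).
#' @noRd
labels_to_onehot <- function(labels, n_classes = 2L) {
  idx <- ifelse(labels == "cancer", 2L, 1L)
  y <- matrix(0, n_classes, length(labels))
  y[cbind(idx, seq_along(labels))] <- 1
  y
}

#' Train a CNN classifier on labelled patches
#'
#' Minimises two-class softmax cross-entropy with Adam. Weights are
#' re-initialised from `hyper$seed` at the start, so the whole run —
#' initialisation, shuffling, dropout — is a deterministic function of
#' (seed, data order). Patches are resized bilinearly to the model input
#' size once, up front.
#'
#' @param model A `cnn_model` from [build_custom_cnn()] or
#'   [build_baseline()].
#' @param patches Patch tibble with list-column `pixels` and a `label`
#'   column containing both classes.
#' @param hyper A [train_config].
#' @param val_patches Optional held-out patch tibble evaluated after each
#'   epoch.
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained `cnn_model`, with `history`: a tibble
#'   `epoch, loss, acc` (+ `val_loss`, `val_acc` when `val_patches` given).
#' @export
train_classifier <- function(model, patches, hyper = train_config(),
                             val_patches = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "cnn_model"))
  labels <- canonical_label(patches$label)
  if (length(unique(labels)) < 2) {
    abort("training data must contain both classes", class = "cxrcad_validation_error")
  }
  n <- nrow(patches)
  x_all <- patches_to_batch(patches$pixels, model$input_size)
  y_all <- labels_to_onehot(labels, model$n_classes)

  with_seed(hyper$seed, {
    init <- nn_init(model$layers, c(model$input_size, model$input_size, 1L))
    params <- init$params
    state <- init$state
    opt_m <- rapply(params, function(a) a * 0, how = "replace")
    opt_v <- opt_m
    t_step <- 0L
    history <- vector("list", hyper$epochs)

    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      losses <- c(); accs <- c()
      for (start in seq(1, n, by = hyper$batch_size)) {
        idx <- ord[start:min(start + hyper$batch_size - 1, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        yb <- y_all[, idx, drop = FALSE]
        fw <- nn_seq_forward(model$layers, params, state, xb, training = TRUE)
        state <- fw$state
        probs <- fw$out
        losses <- c(losses, -mean(log(pmax(colSums(probs * yb), 1e-12))))
        accs <- c(accs, mean(apply(probs, 2, which.max) == apply(yb, 2, which.max)))
        dy <- (probs - yb) / length(idx)
        bw <- nn_seq_backward(model$layers, params, fw$caches, dy)
        t_step <- t_step + 1L
        for (nm in names(bw$grads)) {
          for (part in names(bw$grads[[nm]])) {
            g <- bw$grads[[nm]][[part]]
            opt_m[[nm]][[part]] <- hyper$beta1 * opt_m[[nm]][[part]] + (1 - hyper$beta1) * g
            opt_v[[nm]][[part]] <- hyper$beta2 * opt_v[[nm]][[part]] + (1 - hyper$beta2) * g^2
            mhat <- opt_m[[nm]][[part]] / (1 - hyper$beta1^t_step)
            vhat <- opt_v[[nm]][[part]] / (1 - hyper$beta2^t_step)
            params[[nm]][[part]] <- params[[nm]][[part]] -
              hyper$learning_rate * mhat / (sqrt(vhat) + hyper$epsilon)
          }
        }
      }
      row <- tibble::tibble(epoch = epoch, loss = mean(losses), acc = mean(accs))
      if (!is.null(val_patches)) {
        tmp <- model; tmp$params <- params; tmp$state <- state
        vp <- predict(tmp, val_patches)
        vy <- labels_to_onehot(canonical_label(val_patches$label))
        vprob <- t(as.matrix(vp[, c("p_normal", "p_cancer")]))
        row$val_loss <- -mean(log(pmax(colSums(vprob * vy), 1e-12)))
        row$val_acc <- mean(vp$pred_label == canonical_label(val_patches$label))
      }
      history[[epoch]] <- row
      if (!quiet) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch, row$loss, row$acc))
      }
    }
    # Re-estimate batch-norm running statistics on dropout-free activations:
    # statistics accumulated during training see dropout-noised inputs, which
    # systematically differ from the clean activations inference uses. Enough
    # momentum updates are run for the noisy history to decay away.
    batch_starts <- seq(1, n, by = hyper$batch_size)
    cycles <- max(1L, ceiling(60 / length(batch_starts)))
    for (cycle in seq_len(cycles)) {
      for (start in batch_starts) {
        idx <- start:min(start + hyper$batch_size - 1, n)
        fw <- nn_seq_forward(model$layers, params, state,
                             x_all[, , , idx, drop = FALSE],
                             training = TRUE, dropout_active = FALSE)
        state <- fw$state
      }
    }
    model$params <- params
    model$state <- state
    model$history <- dplyr::bind_rows(history)
    model$trained <- TRUE
    model
  })
}

#' Training history of a fitted model
#'
#' @param model A trained `cnn_model`.
#' @return The per-epoch history tibble.
#' @export
training_history <- function(model) {
  assert_that(!is.null(model$history), "model has no training history")
  model$history
}

#' Plot a model's training history
#'
#' Per-epoch loss and accuracy curves (plus validation curves when the
#' model was trained with `val_patches`).
#'
#' @param model A trained `cnn_model`.
#' @return A ggplot object.
#' @export
plot_history <- function(model) {
  h <- training_history(model)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "series",
                              values_to = "value")
  long$panel <- ifelse(grepl("loss", long$series), "loss", "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_bw()
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file embedding the model configuration,
#' all weights and batch-norm running statistics.
#'
#' @param model A `cnn_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `cnn_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  ser <- list(
    arch = model$arch,
    input_size = model$input_size,
    n_classes = model$n_classes,
    config = unclass(model$config),
    counted_layers = model$counted_layers,
    init_seed = model$init_seed,
    trained = model$trained,
    params = rapply(model$params, function(a) {
      list(dim = dim(a) %||% length(a), data = as.vector(a))
    }, how = "list"),
    state = model$state,
    history = model$history
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (identical(ser$arch, "custom")) {
    cfg <- ser$config
    build_custom_cnn(model_config(
      input_size = cfg$input_size, block_filters = unlist(cfg$block_filters),
      kernel = cfg$kernel, block_stride = cfg$block_stride,
      dropout_rate = cfg$dropout_rate, pooling = cfg$pooling,
      fusion_units = cfg$fusion_units, n_classes = cfg$n_classes
    ), init_seed = ser$init_seed)
  } else {
    build_baseline(ser$arch, input_size = ser$input_size,
                   n_classes = ser$n_classes, init_seed = ser$init_seed)
  }
  for (nm in names(ser$params)) {
    for (part in names(ser$params[[nm]])) {
      entry <- ser$params[[nm]][[part]]
      a <- entry$data
      if (length(entry$dim) > 1) dim(a) <- entry$dim
      model$params[[nm]][[part]] <- a
    }
  }
  for (nm in names(ser$state)) {
    model$state[[nm]] <- lapply(ser$state[[nm]], as.numeric)
  }
  model$trained <- isTRUE(ser$trained)
  if (!is.null(ser$history)) model$history <- tibble::as_tibble(ser$history)
  model
}
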