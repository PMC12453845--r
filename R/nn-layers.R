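# Minimal convolutional-network engine.
#
# Activations are 4-D arrays with dimensions (height, width, channels,
# batch). Convolutions are lowered to matrix multiplication by im2col;
# gradients are hand-derived per layer. This is deliberately a compact,
# CPU-only engine: the networks in this package are small, and matrix
# multiplication through BLAS carries essentially all of the cost.
#
# A network is a nested list of layer descriptions. Trainable parameters
# live in a flat named list keyed by layer name (`params`), batch-norm
# running statistics in a parallel list (`state`), so optimiser updates
# never have to walk the nested structure.

# ---- layer descriptions -----------------------------------------------------

#' @noRd
nn_conv <- function(name, filters, kernel = 3L, stride = 1L, pad = 0L,
                    activation = c("relu", "linear"), edge_pad = FALSE,
                    projection = FALSE) {
  list(type = "conv", name = name, filters = as.integer(filters),
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad), activation = match.arg(activation),
       edge_pad = isTRUE(edge_pad), projection = isTRUE(projection))
}

#' @noRd
nn_bn <- function(name) list(type = "bn", name = name)

#' @noRd
nn_relu <- function() list(type = "relu", name = NULL)

#' @noRd
nn_dropout <- function(name, rate) list(type = "dropout", name = name, rate = rate)

#' @noRd
nn_avgpool <- function(k = 2L) list(type = "avgpool", name = NULL, k = as.integer(k))

#' @noRd
nn_maxpool <- function(k, stride, pad = 0L) {
  list(type = "maxpool", name = NULL, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

#' @noRd
nn_gap <- function() list(type = "gap", name = NULL)

#' @noRd
nn_flatten <- function() list(type = "flatten", name = NULL)

#' @noRd
nn_dense <- function(name, units, activation = c("linear", "relu")) {
  list(type = "dense", name = name, units = as.integer(units),
       activation = match.arg(activation))
}

#' @noRd
nn_softmax <- function() list(type = "softmax", name = NULL)

#' @noRd
nn_residual <- function(name, body, shortcut = NULL) {
  list(type = "residual", name = name, body = body, shortcut = shortcut)
}

#' @noRd
nn_inception <- function(name, branches) {
  list(type = "inception", name = name, branches = branches)
}

# ---- initialisation and shape inference ------------------------------------

# He-normal weight init; consumes the current RNG stream.
#' @noRd
he_init <- function(n_out, fan_in) {
  matrix(rnorm(n_out * fan_in, 0, sqrt(2 / fan_in)), n_out, fan_in)
}

# Walk a layer list, computing output shapes, creating parameters and the
# layer table. `shape` is c(H, W, C) for spatial layers or c(F) after
# flatten. Returns list(params, state, shape, table).
#' @noRd
nn_init <- function(layers, shape, prefix = "") {
  params <- list(); state <- list(); rows <- list()
  for (layer in layers) {
    nm <- if (is.null(layer$name)) layer$type else layer$name
    full <- paste0(prefix, nm)
    n_par <- 0L
    switch(layer$type,
      conv = {
        c_in <- shape[3]; k <- layer$kernel
        params[[layer$name]] <- list(
          W = he_init(layer$filters, k * k * c_in),
          b = numeric(layer$filters)
        )
        hw <- conv_out_extent(shape[1:2], k, layer$stride, layer$pad, layer$edge_pad)
        shape <- c(hw, layer$filters)
        n_par <- k * k * c_in * layer$filters + layer$filters
      },
      bn = {
        c_in <- shape[3]
        params[[layer$name]] <- list(gamma = rep(1, c_in), beta = numeric(c_in))
        state[[layer$name]] <- list(mean = numeric(c_in), var = rep(1, c_in))
        n_par <- 2L * c_in
      },
      dropout = NULL,
      relu = NULL,
      avgpool = {
        assert_that(all(shape[1:2] %% layer$k == 0),
                    sprintf("average pooling needs dimensions divisible by %d, got %d x %d",
                            layer$k, shape[1], shape[2]), "cxrcad_shape_error")
        shape <- c(shape[1:2] %/% layer$k, shape[3])
      },
      maxpool = {
        hw <- conv_out_extent(shape[1:2], layer$k, layer$stride, layer$pad, FALSE)
        shape <- c(hw, shape[3])
      },
      gap = shape <- c(1L, 1L, shape[3]),
      flatten = shape <- prod(shape),
      dense = {
        f_in <- prod(shape)
        params[[layer$name]] <- list(
          W = he_init(layer$units, f_in),
          b = numeric(layer$units)
        )
        shape <- layer$units
        n_par <- f_in * layer$units + layer$units
      },
      softmax = NULL,
      residual = {
        shape_in <- shape
        body <- nn_init(layer$body, shape_in, prefix = paste0(full, "/"))
        params <- c(params, body$params); state <- c(state, body$state)
        rows <- c(rows, body$table)
        if (!is.null(layer$shortcut)) {
          sc <- nn_init(layer$shortcut, shape_in, prefix = paste0(full, "/sc/"))
          params <- c(params, sc$params); state <- c(state, sc$state)
          rows <- c(rows, sc$table)
          assert_that(identical(sc$shape, body$shape),
                      "residual shortcut shape mismatch", "cxrcad_shape_error")
        } else {
          assert_that(identical(as.integer(shape_in), as.integer(body$shape)),
                      "residual identity shortcut needs matching shapes",
                      "cxrcad_shape_error")
        }
        shape <- body$shape
      },
      inception = {
        shape_in <- shape
        outs <- integer(0)
        for (bi in seq_along(layer$branches)) {
          br <- nn_init(layer$branches[[bi]], shape_in,
                        prefix = paste0(full, "/b", bi, "/"))
          params <- c(params, br$params); state <- c(state, br$state)
          rows <- c(rows, br$table)
          assert_that(identical(br$shape[1:2], shape_in[1:2]) || bi == 1,
                      "inception branches must preserve spatial extent",
                      "cxrcad_shape_error")
          outs <- c(outs, br$shape[3])
          sp <- br$shape[1:2]
        }
        shape <- c(sp, sum(outs))
      },
      abort(sprintf("unknown layer type '%s'", layer$type))
    )
    if (!layer$type %in% c("residual", "inception")) {
      rows <- c(rows, list(tibble::tibble(
        name = full, type = layer$type,
        output_shape = paste(shape, collapse = "x"),
        parameters = as.integer(n_par)
      )))
    } else {
      rows <- c(rows, list(tibble::tibble(
        name = full, type = layer$type,
        output_shape = paste(shape, collapse = "x"), parameters = 0L
      )))
    }
  }
  list(params = params, state = state, shape = shape, table = rows)
}

#' @noRd
conv_out_extent <- function(hw, k, stride, pad, edge_pad) {
  hw <- hw + 2L * pad
  if (edge_pad) {
    rem <- (hw - k) %% stride
    hw <- hw + ifelse(rem > 0, stride - rem, 0L)
  }
  assert_that(all(hw >= k), sprintf("window %d exceeds input extent %s", k,
                                    paste(hw, collapse = "x")), "cxrcad_shape_error")
  as.integer((hw - k) %/% stride + 1L)
}

# ---- forward / backward -----------------------------------------------------
#
# Activations are stored channels-first, (C, H, W, N). With channels as the
# fastest-varying dimension, a convolution's GEMM output is already in
# activation layout (no transposes), and per-channel batch-norm arithmetic
# reduces to vector recycling along the first dimension.

#' @noRd
pad_input <- function(x, pad, edge_pad, k, stride) {
  d <- dim(x)
  if (pad > 0) {
    out <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
    out[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
    x <- out
    d <- dim(x)
  }
  if (edge_pad) {
    need_h <- (d[2] - k) %% stride
    need_w <- (d[3] - k) %% stride
    ph <- if (need_h > 0) stride - need_h else 0L
    pw <- if (need_w > 0) stride - need_w else 0L
    if (ph > 0 || pw > 0) {
      out <- array(0, c(d[1], d[2] + ph, d[3] + pw, d[4]))
      out[, seq_len(d[2]), seq_len(d[3]), ] <- x
      if (ph > 0) out[, d[2] + seq_len(ph), seq_len(d[3] + pw), ] <-
        out[, rep(d[2], ph), seq_len(d[3] + pw), , drop = FALSE]
      if (pw > 0) out[, , d[3] + seq_len(pw), ] <-
        out[, , rep(d[3], pw), , drop = FALSE]
      x <- out
    }
  }
  x
}

# im2col: rows ordered (channel, kernel row, kernel col); columns ordered
# (out row, out col, batch) to match column-major layout.
#' @noRd
im2col <- function(x, k, stride) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Ho <- (H - k) %/% stride + 1L; Wo <- (W - k) %/% stride + 1L
  X <- matrix(0, k * k * C, Ho * Wo * N)
  ri <- seq(0L, by = stride, length.out = Ho)
  cj <- seq(0L, by = stride, length.out = Wo)
  at <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    X[at + seq_len(C), ] <- x[, ri + di, cj + dj, ]
    at <- at + C
  }
  X
}

#' @noRd
col2im <- function(dX, dims, k, stride, Ho, Wo) {
  dx <- array(0, dims)
  C <- dims[1]
  ri <- seq(0L, by = stride, length.out = Ho)
  cj <- seq(0L, by = stride, length.out = Wo)
  at <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    dx[, ri + di, cj + dj, ] <- dx[, ri + di, cj + dj, , drop = FALSE] +
      array(dX[at + seq_len(C), ], c(C, Ho, Wo, dims[4]))
    at <- at + C
  }
  dx
}

# Per-channel means of a channels-first array (length-C vector);
# rowMeans(dims = 1) folds all trailing dimensions without a copy.
#' @noRd
channel_means <- function(x, C) {
  rowMeans(x, dims = 1)
}

#' @noRd
layer_forward <- function(layer, params, state, x, training, dropout_active = training) {
  switch(layer$type,
    conv = {
      p <- params[[layer$name]]
      xp <- pad_input(x, layer$pad, layer$edge_pad, layer$kernel, layer$stride)
      dp <- dim(xp)
      Ho <- (dp[2] - layer$kernel) %/% layer$stride + 1L
      Wo <- (dp[3] - layer$kernel) %/% layer$stride + 1L
      X <- im2col(xp, layer$kernel, layer$stride)
      Y <- p$W %*% X + p$b
      if (layer$activation == "relu") Y <- pmax(Y, 0)
      out <- array(Y, c(layer$filters, Ho, Wo, dp[4]))
      list(out = out, cache = list(X = X, Y = Y, dims_pad = dp,
                                   dims_in = dim(x), Ho = Ho, Wo = Wo),
           state = state)
    },
    bn = {
      p <- params[[layer$name]]
      C <- length(p$gamma)
      if (training) {
        mu <- channel_means(x, C)
        v <- channel_means((x - mu)^2, C)
        st <- state[[layer$name]]
        st$mean <- 0.9 * st$mean + 0.1 * mu
        st$var <- 0.9 * st$var + 0.1 * v
        state[[layer$name]] <- st
      } else {
        mu <- state[[layer$name]]$mean
        v <- state[[layer$name]]$var
      }
      inv_std <- 1 / sqrt(v + 1e-5)
      xhat <- (x - mu) * inv_std # length-C vectors recycle along channels
      out <- xhat * p$gamma + p$beta
      list(out = out, cache = list(xhat = xhat, inv_std = inv_std, C = C,
                                   training = training), state = state)
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0), state = state),
    dropout = {
      if (training && dropout_active && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- array(runif(length(x)) < keep, dim(x)) / keep
        list(out = x * mask, cache = list(mask = mask), state = state)
      } else {
        list(out = x, cache = list(mask = NULL), state = state)
      }
    },
    avgpool = {
      k <- layer$k; d <- dim(x)
      acc <- 0
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        acc <- acc + x[, seq(di, d[2], by = k), seq(dj, d[3], by = k), , drop = FALSE]
      }
      list(out = acc / k^2, cache = list(dims = d), state = state)
    },
    maxpool = {
      xp <- pad_input(x, layer$pad, FALSE, layer$k, layer$stride)
      d <- dim(xp)
      Ho <- (d[2] - layer$k) %/% layer$stride + 1L
      Wo <- (d[3] - layer$k) %/% layer$stride + 1L
      ri <- seq(0L, by = layer$stride, length.out = Ho)
      cj <- seq(0L, by = layer$stride, length.out = Wo)
      cur <- array(-Inf, c(d[1], Ho, Wo, d[4]))
      arg <- array(1L, c(d[1], Ho, Wo, d[4]))
      idx <- 0L
      for (dj in seq_len(layer$k)) for (di in seq_len(layer$k)) {
        idx <- idx + 1L
        cand <- xp[, ri + di, cj + dj, , drop = FALSE]
        better <- cand > cur
        cur[better] <- cand[better]
        arg[better] <- idx
      }
      list(out = cur, cache = list(arg = arg, dims_pad = d, dims_in = dim(x),
                                   Ho = Ho, Wo = Wo), state = state)
    },
    gap = {
      d <- dim(x)
      y <- apply(array(x, c(d[1], d[2] * d[3], d[4])), c(1, 3), mean)
      list(out = array(y, c(d[1], 1L, 1L, d[4])), cache = list(dims = d),
           state = state)
    },
    flatten = {
      d <- dim(x)
      dim(x) <- c(prod(d[1:3]), d[4])
      list(out = x, cache = list(dims = d), state = state)
    },
    dense = {
      p <- params[[layer$name]]
      Y <- p$W %*% x + p$b
      if (layer$activation == "relu") Y <- pmax(Y, 0)
      list(out = Y, cache = list(X = x, Y = Y), state = state)
    },
    softmax = {
      z <- sweep(x, 2, apply(x, 2, max))
      e <- exp(z)
      list(out = sweep(e, 2, colSums(e), "/"), cache = NULL, state = state)
    },
    residual = {
      body <- nn_seq_forward(layer$body, params, state, x, training, dropout_active)
      state <- body$state
      if (!is.null(layer$shortcut)) {
        sc <- nn_seq_forward(layer$shortcut, params, state, x, training, dropout_active)
        state <- sc$state
        short <- sc$out
        sc_caches <- sc$caches
      } else {
        short <- x
        sc_caches <- NULL
      }
      out <- pmax(body$out + short, 0)
      list(out = out,
           cache = list(body = body$caches, sc = sc_caches, mask = out > 0),
           state = state)
    },
    inception = {
      outs <- list(); caches <- list()
      for (bi in seq_along(layer$branches)) {
        br <- nn_seq_forward(layer$branches[[bi]], params, state, x, training, dropout_active)
        state <- br$state
        outs[[bi]] <- br$out
        caches[[bi]] <- br$caches
      }
      chans <- vapply(outs, function(o) dim(o)[1], integer(1))
      d1 <- dim(outs[[1]])
      out <- array(0, c(sum(chans), d1[2], d1[3], d1[4]))
      at <- 0L
      for (bi in seq_along(outs)) {
        out[at + seq_len(chans[bi]), , , ] <- outs[[bi]]
        at <- at + chans[bi]
      }
      list(out = out, cache = list(branches = caches, chans = chans),
           state = state)
    },
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
}

#' @noRd
layer_backward <- function(layer, params, cache, dy) {
  grads <- list()
  dx <- switch(layer$type,
    conv = {
      p <- params[[layer$name]]
      dYm <- matrix(dy, nrow = layer$filters)
      if (layer$activation == "relu") dYm <- dYm * (cache$Y > 0)
      grads[[layer$name]] <- list(W = dYm %*% t(cache$X), b = rowSums(dYm))
      dXc <- t(p$W) %*% dYm
      dxp <- col2im(dXc, cache$dims_pad, layer$kernel, layer$stride,
                    cache$Ho, cache$Wo)
      din <- cache$dims_in
      dxp[, layer$pad + seq_len(din[2]), layer$pad + seq_len(din[3]), ,
          drop = FALSE]
    },
    bn = {
      p <- params[[layer$name]]
      C <- cache$C
      grads[[layer$name]] <- list(
        gamma = rowSums(dy * cache$xhat, dims = 1),
        beta = rowSums(dy, dims = 1)
      )
      if (cache$training) {
        (p$gamma * cache$inv_std) *
          (dy - channel_means(dy, C) -
             cache$xhat * channel_means(dy * cache$xhat, C))
      } else {
        dy * (p$gamma * cache$inv_std)
      }
    },
    relu = dy * cache$mask,
    dropout = if (is.null(cache$mask)) dy else dy * cache$mask,
    avgpool = {
      k <- layer$k; d <- cache$dims
      dx <- array(0, d)
      dshare <- dy / k^2
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        dx[, seq(di, d[2], by = k), seq(dj, d[3], by = k), ] <- dshare
      }
      dx
    },
    maxpool = {
      d <- cache$dims_pad
      dxp <- array(0, d)
      ri <- seq(0L, by = layer$stride, length.out = cache$Ho)
      cj <- seq(0L, by = layer$stride, length.out = cache$Wo)
      idx <- 0L
      for (dj in seq_len(layer$k)) for (di in seq_len(layer$k)) {
        idx <- idx + 1L
        sel <- cache$arg == idx
        dxp[, ri + di, cj + dj, ] <- dxp[, ri + di, cj + dj, , drop = FALSE] +
          dy * sel
      }
      din <- cache$dims_in
      dxp[, layer$pad + seq_len(din[2]), layer$pad + seq_len(din[3]), ,
          drop = FALSE]
    },
    gap = {
      d <- cache$dims
      hw <- d[2] * d[3]
      dv <- matrix(dy, d[1]) / hw
      dx <- array(0, d)
      for (n in seq_len(d[4])) dx[, , , n] <- dv[, n] # recycled over (h, w)
      dx
    },
    flatten = array(dy, cache$dims),
    dense = {
      p <- params[[layer$name]]
      dYm <- dy
      if (layer$activation == "relu") dYm <- dYm * (cache$Y > 0)
      grads[[layer$name]] <- list(W = dYm %*% t(cache$X), b = rowSums(dYm))
      t(p$W) %*% dYm
    },
    # combined with cross-entropy: the incoming gradient is already with
    # respect to the logits
    softmax = dy,
    residual = {
      dz <- dy * cache$mask
      body <- nn_seq_backward(layer$body, params, cache$body, dz)
      grads <- c(grads, body$grads)
      if (!is.null(layer$shortcut)) {
        sc <- nn_seq_backward(layer$shortcut, params, cache$sc, dz)
        grads <- c(grads, sc$grads)
        body$dx + sc$dx
      } else {
        body$dx + dz
      }
    },
    inception = {
      at <- 0L
      dx <- NULL
      for (bi in seq_along(layer$branches)) {
        dyb <- dy[at + seq_len(cache$chans[bi]), , , , drop = FALSE]
        at <- at + cache$chans[bi]
        br <- nn_seq_backward(layer$branches[[bi]], params,
                              cache$branches[[bi]], dyb)
        grads <- c(grads, br$grads)
        dx <- if (is.null(dx)) br$dx else dx + br$dx
      }
      dx
    },
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
  list(dx = dx, grads = grads)
}

#' @noRd
nn_seq_forward <- function(layers, params, state, x, training, dropout_active = training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], params, state, x, training, dropout_active)
    x <- res$out
    caches[[i]] <- res$cache
    state <- res$state
  }
  list(out = x, caches = caches, state = state)
}

#' @noRd
nn_seq_backward <- function(layers, params, caches, dy) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    res <- layer_backward(layers[[i]], params, caches[[i]], dy)
    dy <- res$dx
    grads <- c(grads, res$grads)
  }
  list(dx = dy, grads = grads)
}
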