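#' @title Minimal 3D conv-net engine
#' @name nn_engine
#' @description A compact, fully deterministic 3D convolutional network
#'   engine: feature maps are channels-x-voxels matrices, convolutions run as
#'   im2col + BLAS GEMM (see `src/conv_ops.cpp`), and every layer implements
#'   an explicit hand-derived backward pass. Networks are flat op lists; skip
#'   connections use save/concat ops so the same machinery drives both the
#'   U-Net segmenter and the GAN generators/discriminators.
#'
#'   Normalization layers use the statistics of the current volume in both
#'   training and inference (instance-style normalization), which keeps
#'   inference deterministic and robust to the intensity-scale differences
#'   typical of fluorescence volumes.
NULL

# --- layer constructors -----------------------------------------------------

nn_conv <- function(c_in, c_out) {
  W <- matrix(rnorm(c_out * c_in * 27, sd = sqrt(2 / (27 * c_in))),
              nrow = c_out)
  list(type = "conv", W = W, b = rep(0, c_out), c_in = c_in, c_out = c_out)
}

nn_bn <- function(c_ch, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c_ch), beta = rep(0, c_ch), eps = eps)
}

nn_lrelu <- function(slope = 0.01) list(type = "lrelu", slope = slope)

nn_pool <- function() list(type = "pool")

nn_upconv <- function(c_in, c_out) {
  W <- matrix(rnorm(c_out * c_in * 8, sd = sqrt(2 / (8 * c_in))),
              nrow = c_out)
  list(type = "upconv", W = W, b = rep(0, c_out), c_in = c_in, c_out = c_out)
}

nn_sigmoid <- function() list(type = "sigmoid")

nn_save <- function() list(type = "save")

nn_concat <- function() list(type = "concat")

# --- forward / backward -----------------------------------------------------

# x: C x N matrix; dims: integer (z, y, x) with prod(dims) == N.
layer_forward <- function(layer, x, dims) {
  switch(layer$type,
    conv = {
      cols <- nsg_im2col3(x, dims[1], dims[2], dims[3])
      y <- layer$W %*% cols + layer$b
      list(y = y, dims = dims, cache = list(cols = cols, dims = dims))
    },
    bn = {
      mu <- rowMeans(x)
      v <- rowMeans(x^2) - mu^2
      istd <- 1 / sqrt(v + layer$eps)
      xhat <- (x - mu) * istd
      list(y = xhat * layer$gamma + layer$beta, dims = dims,
           cache = list(xhat = xhat, istd = istd))
    },
    lrelu = {
      neg <- x < 0
      y <- x
      y[neg] <- layer$slope * x[neg]
      list(y = y, dims = dims, cache = list(neg = neg))
    },
    pool = {
      r <- nsg_maxpool3_fwd(x, dims[1], dims[2], dims[3])
      list(y = r$out, dims = dims %/% 2L,
           cache = list(argmax = r$argmax, n_in = ncol(x)))
    },
    upconv = {
      y <- nsg_upconv3_fwd(x, layer$W, layer$b, dims[1], dims[2], dims[3])
      list(y = y, dims = dims * 2L, cache = list(x = x, dims = dims))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, dims = dims, cache = list(y = y))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, dy, cache) {
  switch(layer$type,
    conv = {
      dW <- dy %*% t(cache$cols)
      db <- rowSums(dy)
      dcols <- t(layer$W) %*% dy
      dx <- nsg_col2im3(dcols, cache$dims[1], cache$dims[2], cache$dims[3],
                        layer$c_in)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    bn = {
      xhat <- cache$xhat
      dgamma <- rowSums(dy * xhat)
      dbeta <- rowSums(dy)
      dxhat <- dy * layer$gamma
      dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
        cache$istd
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = {
      dx <- dy
      dx[cache$neg] <- layer$slope * dy[cache$neg]
      list(dx = dx, grads = NULL)
    },
    pool = {
      list(dx = nsg_maxpool3_bwd(dy, cache$argmax, cache$n_in), grads = NULL)
    },
    upconv = {
      r <- nsg_upconv3_bwd(dy, cache$x, layer$W,
                           cache$dims[1], cache$dims[2], cache$dims[3])
      list(dx = r$dX, grads = list(W = r$dW, b = as.vector(r$db)))
    },
    sigmoid = {
      y <- cache$y
      list(dx = dy * y * (1 - y), grads = NULL)
    },
    stop("unknown layer type: ", layer$type))
}

#' Run a network forward
#'
#' @param net list with `ops` (layer list, possibly containing save/concat).
#' @param x input feature matrix (channels x voxels).
#' @param dims integer (z, y, x) spatial dims of `x`.
#' @return list(out, dims, caches) where caches feed [net_backward()].
#' @keywords internal
net_forward <- function(net, x, dims) {
  caches <- vector("list", length(net$ops))
  stack <- list()
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    if (op$type == "save") {
      stack[[length(stack) + 1]] <- list(x = x, dims = dims)
      caches[[i]] <- list(type = "save")
    } else if (op$type == "concat") {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (!all(top$dims == dims))
        stop("concat: skip dims ", paste(top$dims, collapse = "x"),
             " != current dims ", paste(dims, collapse = "x"))
      caches[[i]] <- list(type = "concat", c_up = nrow(x))
      x <- rbind(x, top$x)
    } else {
      r <- layer_forward(op, x, dims)
      x <- r$y
      dims <- r$dims
      caches[[i]] <- r$cache
    }
  }
  list(out = x, dims = dims, caches = caches)
}

#' Back-propagate through a network
#'
#' @param net the network whose forward produced `caches`.
#' @param caches from [net_forward()].
#' @param dy gradient of the loss w.r.t. the network output.
#' @return list(dx, grads) with `grads` parallel to `net$ops`.
#' @keywords internal
net_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$ops))
  pending <- list()   # gradients waiting for their save op (LIFO)
  for (i in rev(seq_along(net$ops))) {
    op <- net$ops[[i]]
    if (op$type == "save") {
      dskip <- pending[[length(pending)]]
      pending[[length(pending)]] <- NULL
      dy <- dy + dskip
    } else if (op$type == "concat") {
      c_up <- caches[[i]]$c_up
      pending[[length(pending) + 1]] <-
        dy[(c_up + 1):nrow(dy), , drop = FALSE]
      dy <- dy[seq_len(c_up), , drop = FALSE]
    } else {
      r <- layer_backward(op, dy, caches[[i]])
      dy <- r$dx
      grads[i] <- list(r$grads)
    }
  }
  list(dx = dy, grads = grads)
}

# --- parameters & Adam ------------------------------------------------------

param_fields <- function(layer) {
  switch(layer$type, conv = c("W", "b"), upconv = c("W", "b"),
         bn = c("gamma", "beta"), character(0))
}

#' Total trainable parameter count of a network
#' @param net a network.
#' @return integer count.
#' @keywords internal
nn_param_count <- function(net) {
  sum(vapply(net$ops, function(op)
    sum(vapply(param_fields(op), function(f) length(op[[f]]), numeric(1))),
    numeric(1)))
}

nn_zero_grads <- function(net) {
  lapply(net$ops, function(op) {
    pf <- param_fields(op)
    if (!length(pf)) return(NULL)
    setNames(lapply(pf, function(f) 0 * op[[f]]), pf)
  })
}

nn_add_grads <- function(acc, g) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (f in names(g[[i]])) acc[[i]][[f]] <- acc[[i]][[f]] + g[[i]][[f]]
  }
  acc
}

nn_scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (f in names(g[[i]])) g[[i]][[f]] <- g[[i]][[f]] * s
  }
  g
}

nn_init_adam <- function(net) {
  lapply(net$ops, function(op) {
    pf <- param_fields(op)
    if (!length(pf)) return(NULL)
    setNames(lapply(pf, function(f)
      list(m = 0 * op[[f]], v = 0 * op[[f]])), pf)
  })
}

# One Adam update; returns list(net, state).
nn_adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, t = 1) {
  for (i in seq_along(net$ops)) {
    if (is.null(grads[[i]])) next
    for (f in names(grads[[i]])) {
      g <- grads[[i]][[f]]
      st <- state[[i]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$ops[[i]][[f]] <- net$ops[[i]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[f]] <- st
    }
  }
  list(net = net, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert a (z,y,x) array to a 1 x N feature matrix and back.
vol_to_feat <- function(v) matrix(as.vector(v), nrow = 1)
feat_to_vol <- function(m, dims) array(as.vector(m), dim = dims)
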