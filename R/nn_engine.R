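# A compact conv-net engine: sequential layers over (H, W, C, N) arrays,
# with analytic backward passes and a flat-vector Adam optimizer. Heavy
# kernels (convolution, pooling, resizing) live in src/nn_ops.cpp; dense
# algebra uses BLAS via base matrix products.

layer_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L) {
  fan_in <- kernel * kernel * in_ch
  W <- array(rnorm(kernel * kernel * in_ch * out_ch, 0, sqrt(2 / fan_in)),
             dim = c(kernel, kernel, in_ch, out_ch))
  list(type = "conv", W = W, b = numeric(out_ch),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch),
       momentum = momentum, eps = eps)
}

layer_relu <- function() list(type = "relu")

layer_maxpool <- function(size = 2L, stride = size)
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride))

layer_gap <- function() list(type = "gap")

layer_residual <- function(layers, shortcut = list())
  list(type = "residual", layers = layers, shortcut = shortcut)

# channel-wise statistics helpers for BN over (H, W, C, N)
bn_moments <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  list(mean = colMeans(xm), var = colMeans(xm^2) - colMeans(xm)^2, mat = xm)
}

layer_forward <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      out <- conv2d_forward_cpp(x, dim(x), layer$W, dim(layer$W), layer$b,
                                layer$stride, layer$pad)
      list(out = out, cache = list(x = x))
    },
    bn = {
      d <- dim(x)
      if (train) {
        mo <- bn_moments(x)
        mu <- mo$mean; v <- mo$var
      } else {
        mu <- layer$running_mean; v <- layer$running_var
      }
      scale <- layer$gamma / sqrt(v + layer$eps)
      shift <- layer$beta - mu * scale
      out <- sweep(sweep(x, 3, scale, "*"), 3, shift, "+")
      list(out = out, cache = list(x = x, mu = mu, v = v, train = train))
    },
    relu = {
      out <- x * (x > 0)
      list(out = out, cache = list(mask = x > 0))
    },
    maxpool = {
      r <- maxpool_forward_cpp(x, dim(x), layer$size, layer$stride)
      list(out = r$out, cache = list(arg = r$arg, xdim = dim(x)))
    },
    gap = {
      d <- dim(x)
      xm <- aperm(x, c(1, 2, 4, 3))
      dim(xm) <- c(d[1] * d[2], d[4] * d[3])
      m <- colMeans(xm)
      out <- matrix(m, nrow = d[4], ncol = d[3])  # N x C
      list(out = out, cache = list(xdim = d))
    },
    residual = {
      main <- seq_forward(layer$layers, x, train)
      if (length(layer$shortcut)) {
        sc <- seq_forward(layer$shortcut, x, train)
        out <- main$out + sc$out
        list(out = out * (out > 0),
             cache = list(main = main$caches, sc = sc$caches,
                          mask = out > 0, has_sc = TRUE))
      } else {
        out <- main$out + x
        list(out = out * (out > 0),
             cache = list(main = main$caches, mask = out > 0, has_sc = FALSE))
      }
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      g <- conv2d_backward_cpp(cache$x, dim(cache$x), layer$W, dim(layer$W),
                               dout, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(W = g$dW, b = g$db))
    },
    bn = {
      d <- dim(cache$x)
      n <- d[1] * d[2] * d[4]
      inv_sd <- 1 / sqrt(cache$v + layer$eps)
      xc <- sweep(cache$x, 3, cache$mu, "-")
      xhat <- sweep(xc, 3, inv_sd, "*")
      ax <- function(a) {  # sum over all but channel dim
        am <- aperm(a, c(1, 2, 4, 3))
        dim(am) <- c(n, d[3])
        colSums(am)
      }
      dgamma <- ax(dout * xhat)
      dbeta <- ax(dout)
      if (cache$train) {
        dxhat <- sweep(dout, 3, layer$gamma, "*")
        sum_dxhat <- ax(dxhat)
        sum_dxhat_xhat <- ax(dxhat * xhat)
        dx <- sweep(dxhat, 3, sum_dxhat / n, "-") -
          xhat * sweep(array(1, d), 3, sum_dxhat_xhat / n, "*")
        dx <- sweep(dx, 3, inv_sd, "*")
      } else {
        dx <- sweep(dout, 3, layer$gamma * inv_sd, "*")
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    maxpool = list(dx = maxpool_backward_cpp(dout, cache$arg, cache$xdim),
                   grads = NULL),
    gap = {
      d <- cache$xdim
      # dout is N x C; spread evenly over H*W
      dx <- array(0, d)
      per <- dout / (d[1] * d[2])
      for (c in seq_len(d[3]))
        dx[, , c, ] <- array(rep(per[, c], each = d[1] * d[2]),
                             dim = c(d[1], d[2], d[4]))
      list(dx = dx, grads = NULL)
    },
    residual = {
      dpre <- dout * cache$mask
      main <- seq_backward(layer$layers, cache$main, dpre)
      if (cache$has_sc) {
        sc <- seq_backward(layer$shortcut, cache$sc, dpre)
        list(dx = main$dx + sc$dx,
             grads = list(main = main$grads, sc = sc$grads))
      } else {
        list(dx = main$dx + dpre, grads = list(main = main$grads))
      }
    },
    stop("unknown layer type ", layer$type))
}

seq_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # preserve NULL entries for param-free layers
  }
  list(dx = dout, grads = grads)
}

# --- flat parameter vector plumbing -------------------------------------

param_names <- function(layer)
  switch(layer$type, conv = c("W", "b"), bn = c("gamma", "beta"),
         character())

layers_param_vector <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "residual") {
      out[[length(out) + 1L]] <- layers_param_vector(l$layers)
      if (length(l$shortcut))
        out[[length(out) + 1L]] <- layers_param_vector(l$shortcut)
    } else {
      for (p in param_names(l)) out[[length(out) + 1L]] <- as.numeric(l[[p]])
    }
  }
  if (length(out)) unlist(out) else numeric(0)
}

layers_set_param_vector <- function(layers, v, offset = 0L) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "residual") {
      r <- layers_set_param_vector(l$layers, v, offset)
      layers[[i]]$layers <- r$layers
      offset <- r$offset
      if (length(l$shortcut)) {
        r <- layers_set_param_vector(l$shortcut, v, offset)
        layers[[i]]$shortcut <- r$layers
        offset <- r$offset
      }
    } else {
      for (p in param_names(l)) {
        n <- length(l[[p]])
        val <- v[(offset + 1L):(offset + n)]
        if (!is.null(dim(l[[p]]))) dim(val) <- dim(l[[p]])
        layers[[i]][[p]] <- val
        offset <- offset + n
      }
    }
  }
  list(layers = layers, offset = offset)
}

layers_grad_vector <- function(layers, grads) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (l$type == "residual") {
      out[[length(out) + 1L]] <- layers_grad_vector(l$layers, g$main)
      if (length(l$shortcut))
        out[[length(out) + 1L]] <- layers_grad_vector(l$shortcut, g$sc)
    } else {
      for (p in param_names(l)) out[[length(out) + 1L]] <- as.numeric(g[[p]])
    }
  }
  if (length(out)) unlist(out) else numeric(0)
}

# --- Adam ----------------------------------------------------------------

adam_init <- function(n, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0)
  list(m = numeric(n), v = numeric(n), t = 0L, lr = lr,
       beta1 = beta1, beta2 = beta2, eps = eps, wd = weight_decay)

# Adam with decoupled (AdamW-style) weight decay
adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grads
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grads^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  step <- state$lr * mhat / (sqrt(vhat) + state$eps)
  if (state$wd > 0) step <- step + state$lr * state$wd * params
  list(state = state, params = params - step)
}
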