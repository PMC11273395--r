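# Minimal convolutional network core used by the VQ-VAE, the
# autoregressive prior and the Bayesian U-Net. Tensors are numeric arrays
# with dim (H, W, C); a plain matrix is treated as (H, W, 1). Layers are
# environments holding parameters, accumulated gradients and the forward
# cache; models process one image at a time and mini-batches accumulate
# gradients before an Adam step. All analytic gradients are checked
# against finite differences in the test suite.

as_hwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$grads <- list()
  e$opt <- list()
  class(e) <- c(class, "nn_layer")
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- primitive layers -------------------------------------------------

# k x k convolution; weights (k*k*cin) x cout; optional binary weight mask
# (same shape as W) for causal/masked convolutions.
nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    mask = NULL) {
  new_layer("nn_conv",
    W = he_init(k * k * cin, cout, fan_in = k * k * cin),
    b = numeric(cout),
    k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
    cin = as.integer(cin), cout = as.integer(cout), mask = mask,
    param_names = c("W", "b"))
}

# 2x2 stride-2 transpose convolution (exact x2 upsampling);
# weights cin x (4*cout), parity block t = a + 2b.
nn_tconv2 <- function(cin, cout) {
  new_layer("nn_tconv2",
    W = he_init(cin, 4L * cout, fan_in = cin),
    b = numeric(cout),
    cin = as.integer(cin), cout = as.integer(cout),
    param_names = c("W", "b"))
}

nn_relu <- function() new_layer("nn_relu", param_names = character())

nn_maxpool2 <- function() new_layer("nn_maxpool2", param_names = character())

# Per-channel normalisation over the spatial dimensions (the batch here is
# a single image, so train-time statistics are spatial); running moments
# are kept for inference.
nn_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("nn_batchnorm",
    gamma = rep(1, channels), beta = numeric(channels),
    run_mean = numeric(channels), run_var = rep(1, channels),
    momentum = momentum, eps = eps, channels = as.integer(channels),
    param_names = c("gamma", "beta"))
}

# Inverted dropout: active when training or when mc (Monte-Carlo) mode is
# switched on for epistemic-uncertainty sampling.
nn_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  new_layer("nn_dropout", p = p, mc = FALSE, param_names = character())
}

## ---- containers -------------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) layers <- layers[[1]]
  new_layer("nn_sequential", layers = layers, param_names = character())
}

# x + body(x); the body must preserve shape.
nn_residual <- function(...) {
  body <- nn_sequential(...)
  new_layer("nn_residual", body = body, param_names = character())
}

## ---- forward ----------------------------------------------------------

# Explicit dispatch (no S3 registration needed for internal generics).
nn_forward <- function(layer, x, training = FALSE) {
  switch(class(layer)[1],
    nn_conv = nn_forward.nn_conv(layer, x, training),
    nn_tconv2 = nn_forward.nn_tconv2(layer, x, training),
    nn_relu = nn_forward.nn_relu(layer, x, training),
    nn_maxpool2 = nn_forward.nn_maxpool2(layer, x, training),
    nn_batchnorm = nn_forward.nn_batchnorm(layer, x, training),
    nn_dropout = nn_forward.nn_dropout(layer, x, training),
    nn_sequential = nn_forward.nn_sequential(layer, x, training),
    nn_residual = nn_forward.nn_residual(layer, x, training),
    stop("unknown layer class: ", class(layer)[1]))
}

nn_forward.nn_conv <- function(layer, x, training = FALSE) {
  x <- as_hwc(x)
  W <- if (is.null(layer$mask)) layer$W else layer$W * layer$mask
  r <- conv_fwd_cpp(x, W, layer$b, layer$k, layer$stride, layer$pad)
  layer$cache <- list(cols = r$cols, dims = dim(x))
  r$out
}

nn_forward.nn_tconv2 <- function(layer, x, training = FALSE) {
  x <- as_hwc(x)
  layer$cache <- list(x = x)
  tconv2_fwd_cpp(x, layer$W, layer$b)
}

nn_forward.nn_relu <- function(layer, x, training = FALSE) {
  out <- pmax(x, 0)
  layer$cache <- list(pos = x > 0)
  out
}

nn_forward.nn_maxpool2 <- function(layer, x, training = FALSE) {
  x <- as_hwc(x)
  r <- maxpool2_fwd_cpp(x)
  layer$cache <- list(argmax = r$argmax, H = dim(x)[1], W = dim(x)[2])
  r$out
}

nn_forward.nn_batchnorm <- function(layer, x, training = FALSE) {
  x <- as_hwc(x)
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv_sd <- 1 / sqrt(pmax(v, 0) + layer$eps)
  xhat <- xm
  out <- xm
  for (ch in seq_len(d[3])) {   # per-channel column ops avoid big temporaries
    xhat[, ch] <- (xm[, ch] - mu[ch]) * inv_sd[ch]
    out[, ch] <- xhat[, ch] * layer$gamma[ch] + layer$beta[ch]
  }
  layer$cache <- list(xhat = xhat, inv_sd = inv_sd, dims = d,
                      training = training)
  array(out, d)
}

nn_forward.nn_dropout <- function(layer, x, training = FALSE) {
  if ((training || isTRUE(layer$mc)) && layer$p > 0) {
    keep <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
    layer$cache <- list(keep = keep)
    array(x * keep, dim(as_hwc(x)))
  } else {
    layer$cache <- list(keep = NULL)
    x
  }
}

nn_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, training)
  x
}

nn_forward.nn_residual <- function(layer, x, training = FALSE) {
  as_hwc(x) + nn_forward(layer$body, x, training)
}

## ---- backward ---------------------------------------------------------
# Each backward consumes the layer's forward cache, accumulates parameter
# gradients (+=) and returns the gradient w.r.t. its input.

acc_grad <- function(layer, name, g) {
  cur <- layer$grads[[name]]
  layer$grads[[name]] <- if (is.null(cur)) g else cur + g
}

nn_backward <- function(layer, dout) {
  switch(class(layer)[1],
    nn_conv = nn_backward.nn_conv(layer, dout),
    nn_tconv2 = nn_backward.nn_tconv2(layer, dout),
    nn_relu = nn_backward.nn_relu(layer, dout),
    nn_maxpool2 = nn_backward.nn_maxpool2(layer, dout),
    nn_batchnorm = nn_backward.nn_batchnorm(layer, dout),
    nn_dropout = nn_backward.nn_dropout(layer, dout),
    nn_sequential = nn_backward.nn_sequential(layer, dout),
    nn_residual = nn_backward.nn_residual(layer, dout),
    stop("unknown layer class: ", class(layer)[1]))
}

nn_backward.nn_conv <- function(layer, dout) {
  cc <- layer$cache
  W <- if (is.null(layer$mask)) layer$W else layer$W * layer$mask
  r <- conv_bwd_cpp(as_hwc(dout), cc$cols, W, cc$dims[1], cc$dims[2],
                    cc$dims[3], layer$k, layer$stride, layer$pad)
  dW <- if (is.null(layer$mask)) r$dW else r$dW * layer$mask
  acc_grad(layer, "W", dW)
  acc_grad(layer, "b", as.numeric(r$db))
  r$dx
}

nn_backward.nn_tconv2 <- function(layer, dout) {
  r <- tconv2_bwd_cpp(as_hwc(dout), layer$cache$x, layer$W)
  acc_grad(layer, "W", r$dW)
  acc_grad(layer, "b", as.numeric(r$db))
  r$dx
}

nn_backward.nn_relu <- function(layer, dout) {
  dout * layer$cache$pos
}

nn_backward.nn_maxpool2 <- function(layer, dout) {
  cc <- layer$cache
  maxpool2_bwd_cpp(as_hwc(dout), cc$argmax, cc$H, cc$W)
}

nn_backward.nn_batchnorm <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$dims
  n <- d[1] * d[2]
  dm <- matrix(dout, n, d[3])
  acc_grad(layer, "gamma", colSums(dm * cc$xhat))
  acc_grad(layer, "beta", colSums(dm))
  dx <- dm
  if (cc$training) {
    for (ch in seq_len(d[3])) {
      dxh <- dm[, ch] * layer$gamma[ch]
      dx[, ch] <- (dxh - mean(dxh) -
                     cc$xhat[, ch] * mean(dxh * cc$xhat[, ch])) *
        cc$inv_sd[ch]
    }
  } else {
    for (ch in seq_len(d[3])) {
      dx[, ch] <- dm[, ch] * layer$gamma[ch] * cc$inv_sd[ch]
    }
  }
  array(dx, d)
}

nn_backward.nn_dropout <- function(layer, dout) {
  keep <- layer$cache$keep
  if (is.null(keep)) dout else array(dout * keep, dim(as_hwc(dout)))
}

nn_backward.nn_sequential <- function(layer, dout) {
  for (l in rev(layer$layers)) dout <- nn_backward(l, dout)
  dout
}

nn_backward.nn_residual <- function(layer, dout) {
  dout + nn_backward(layer$body, dout)
}

## ---- parameter walking and Adam ---------------------------------------

# Flatten a module tree into the list of primitive layers with parameters.
nn_collect <- function(module) {
  if (inherits(module, "nn_sequential")) {
    unlist(lapply(module$layers, nn_collect), recursive = FALSE)
  } else if (inherits(module, "nn_residual")) {
    nn_collect(module$body)
  } else if (inherits(module, "nn_layer")) {
    if (length(module$param_names)) list(module) else list()
  } else if (is.list(module)) {
    unlist(lapply(module, nn_collect), recursive = FALSE)
  } else {
    list()
  }
}

nn_zero_grads <- function(layers) {
  for (l in layers) l$grads <- list()
  invisible(NULL)
}

# One Adam update over accumulated gradients; `scale` divides the
# accumulated gradient (mini-batch averaging), `t` is the step counter.
adam_step <- function(layers, lr, t, scale = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    for (nm in l$param_names) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      g <- g / scale
      st <- l$opt[[nm]]
      if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l[[nm]] <- l[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      l$opt[[nm]] <- st
    }
  }
  invisible(NULL)
}

# Switch Monte-Carlo dropout mode on/off across a module tree.
nn_set_mc <- function(module, mc) {
  walk <- function(m) {
    if (inherits(m, "nn_dropout")) m$mc <- mc
    if (inherits(m, "nn_sequential")) lapply(m$layers, walk)
    if (inherits(m, "nn_residual")) walk(m$body)
    if (is.list(m) && !inherits(m, "nn_layer")) lapply(m, walk)
    invisible(NULL)
  }
  walk(module)
  invisible(NULL)
}
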