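# Bayesian U-Net for vessel segmentation with Monte-Carlo-dropout
# epistemic uncertainty.
#
# A dropout-equipped U-Net is trained on healthy en face images to
# segment the vasculature against weak (automatically generated) labels.
# On abnormal anatomy the model has no training support, so keeping
# dropout active at test time and sampling n stochastic predictions
# yields high prediction variance exactly where the vasculature is
# unusual: the per-pixel, per-class population variance averaged over the
# two classes is the epistemic uncertainty map used for anomaly scoring
# and segmentation.

#' Bayesian U-Net configuration
#'
#' Each convolutional block is 3x3 convolution + batch normalisation +
#' ReLU + dropout; encoder levels downsample with 2x2 max pooling and the
#' decoder upsamples with transpose convolutions, concatenating skip
#' connections. The `paper` preset is the full-scale architecture (depth
#' 5, 64 channels per block, 200 epochs); `desk` shrinks to depth 4 and
#' 8 base channels for 128-px phantoms.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param depth Number of resolution levels (encoder + mirrored decoder).
#' @param base_channels Channels at the top level (doubled per level).
#' @param dropout_p Dropout probability after every conv block; must be
#'   positive for epistemic uncertainty to be defined.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param beta Weight of the Dice term in the loss (cross-entropy +
#'   beta * Dice), default 0.6.
#' @param class_weights Length-2 cross-entropy weights
#'   (background, vessel).
#' @param n_mc Default number of Monte-Carlo dropout samples.
#' @param rng_seed Integer seed.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(preset = c("desk", "paper"),
                        depth = NULL,
                        base_channels = NULL,
                        dropout_p = 0.1,
                        learning_rate = 5e-4,
                        epochs = NULL,
                        batch_size = 4L,
                        beta = 0.6,
                        class_weights = c(1, 1),
                        n_mc = 20L,
                        rng_seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "desk") {
    list(depth = 4L, base_channels = 8L, epochs = 6L)
  } else {
    list(depth = 5L, base_channels = 64L, epochs = 200L)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(preset = preset,
              depth = as.integer(pick(depth, def$depth)),
              base_channels = as.integer(pick(base_channels,
                                              def$base_channels)),
              dropout_p = dropout_p,
              learning_rate = learning_rate,
              epochs = as.integer(pick(epochs, def$epochs)),
              batch_size = as.integer(batch_size),
              beta = beta,
              class_weights = as.numeric(class_weights),
              n_mc = as.integer(n_mc),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$depth >= 2, cfg$beta >= 0, cfg$dropout_p >= 0,
            cfg$dropout_p < 1, length(cfg$class_weights) == 2)
  structure(cfg, class = "unet_config")
}

unet_block <- function(cin, cout, p) {
  nn_sequential(nn_conv(cin, cout, 3), nn_batchnorm(cout), nn_relu(),
                nn_dropout(p))
}

#' Build an untrained Bayesian U-Net
#'
#' @param cfg A [unet_config()].
#' @return A `unet_model` list holding encoder blocks, pools, bottleneck,
#'   up-convolutions and decoder blocks.
#' @export
unet_model <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  with_seed(cfg$rng_seed, {
    d <- cfg$depth
    ch <- cfg$base_channels * 2L^(seq_len(d) - 1L)
    enc <- vector("list", d - 1L)
    cin <- 1L
    for (i in seq_len(d - 1L)) {
      enc[[i]] <- nn_sequential(unet_block(cin, ch[i], cfg$dropout_p),
                                unet_block(ch[i], ch[i], cfg$dropout_p))
      cin <- ch[i]
    }
    bottleneck <- nn_sequential(unet_block(cin, ch[d], cfg$dropout_p),
                                unet_block(ch[d], ch[d], cfg$dropout_p))
    pools <- lapply(seq_len(d - 1L), function(i) nn_maxpool2())
    ups <- vector("list", d - 1L)
    dec <- vector("list", d - 1L)
    for (i in rev(seq_len(d - 1L))) {
      ups[[i]] <- nn_tconv2(ch[i + 1L], ch[i])
      dec[[i]] <- nn_sequential(unet_block(2L * ch[i], ch[i],
                                           cfg$dropout_p),
                                unet_block(ch[i], ch[i], cfg$dropout_p))
    }
    head <- nn_conv(ch[1], 2L, 1, pad = 0L)
    structure(list(enc = enc, pools = pools, bottleneck = bottleneck,
                   ups = ups, dec = dec, head = head, config = cfg),
              class = "unet_model")
  })
}

unet_layers <- function(model) {
  c(nn_collect(model$enc), nn_collect(model$bottleneck),
    nn_collect(model$ups), nn_collect(model$dec), nn_collect(model$head))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# Forward pass returning per-pixel class probabilities (background,
# vessel) via softmax; caches are stored in the layers for backward.
unet_forward <- function(model, x, training = FALSE) {
  d <- model$config$depth
  skips <- vector("list", d - 1L)
  h <- as_hwc(x)
  for (i in seq_len(d - 1L)) {
    h <- nn_forward(model$enc[[i]], h, training)
    skips[[i]] <- h
    h <- nn_forward(model$pools[[i]], h, training)
  }
  h <- nn_forward(model$bottleneck, h, training)
  for (i in rev(seq_len(d - 1L))) {
    h <- nn_forward(model$ups[[i]], h, training)
    h <- concat_channels(skips[[i]], h)
    h <- nn_forward(model$dec[[i]], h, training)
  }
  logits <- nn_forward(model$head, h, training)
  dm <- dim(logits)
  lm <- matrix(logits, dm[1] * dm[2], 2)
  mx <- pmax(lm[, 1], lm[, 2])
  ez <- exp(lm - mx)
  probs <- ez / rowSums(ez)
  array(probs, dm)
}

#' Segmentation loss: cross-entropy + beta * Dice loss
#'
#' `CE + beta * (1 - Dice)` where CE is the (optionally class-weighted)
#' mean pixel cross-entropy of the predicted vessel probability against
#' the binary label and Dice is the soft Dice coefficient of the vessel
#' class.
#'
#' @param pred Matrix of vessel-class probabilities in `[0, 1]`.
#' @param weak_label Binary matrix (vessel = 1).
#' @param beta Dice-term weight (>= 0), default 0.6.
#' @param class_weights Length-2 weights (background, vessel) for the
#'   cross-entropy term.
#' @param eps Probability clipping floor.
#' @return A single nonnegative number.
#' @export
seg_loss <- function(pred, weak_label, beta = 0.6,
                     class_weights = c(1, 1), eps = 1e-7) {
  if (!identical(dim(pred), dim(weak_label))) {
    stop("prediction and label shapes differ", call. = FALSE)
  }
  stopifnot(beta >= 0)
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.numeric(weak_label)
  w <- ifelse(y > 0.5, class_weights[2], class_weights[1])
  ce <- -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
  dice <- (2 * sum(p * y)) / (sum(p) + sum(y) + eps)
  ce + beta * (1 - dice)
}

#' Train the Bayesian U-Net on healthy images with vessel weak labels
#'
#' @param manifest Dataset manifest; the healthy train split must carry
#'   vessel masks. Alternatively pass `images` and `masks` directly.
#' @param cfg A [unet_config()].
#' @param images,masks Optional preloaded lists overriding the manifest.
#' @param enhance Optional [preprocess_config()]; when given, inputs are
#'   vesselness-enhanced before training (the segmentation path benefits
#'   from ridge enhancement).
#' @param verbose Print per-epoch losses.
#' @return A trained `unet_model` with `history` attached.
#' @export
train_unet <- function(manifest, cfg, images = NULL, masks = NULL,
                       enhance = NULL, verbose = FALSE) {
  if (is.null(images)) {
    validate_manifest(manifest)
    tr <- manifest[manifest$split == "train" &
                     manifest$label == "healthy", ]
    if (nrow(tr) == 0) stop("train split is empty", call. = FALSE)
    if (any(tr$vessel_mask == "")) {
      stop("missing vessel mask in train split", call. = FALSE)
    }
    idx <- which(manifest$split == "train" & manifest$label == "healthy")
    images <- lapply(idx, function(i)
      load_image(manifest_path(manifest, "image", i)))
    masks <- lapply(idx, function(i)
      load_image(manifest_path(manifest, "vessel_mask", i)) > 0.5)
  }
  stopifnot(length(images) == length(masks), length(images) > 0)
  if (!is.null(enhance)) {
    images <- lapply(images, vesselness_enhance, cfg = enhance)
  }
  model <- unet_model(cfg)
  layers <- unet_layers(model)
  history <- data.frame(epoch = integer(), loss = numeric())
  with_seed(cfg$rng_seed + 1L, {
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(images))
      ep_loss <- 0
      bcount <- 0L
      nn_zero_grads(layers)
      for (t in seq_along(ord)) {
        x <- images[[ord[t]]]
        y <- masks[[ord[t]]] * 1
        probs <- unet_forward(model, x, training = TRUE)
        pv <- matrix(probs[, , 2], nrow(x), ncol(x))
        ep_loss <- ep_loss + seg_loss(pv, y, cfg$beta, cfg$class_weights)
        dlogits <- seg_loss_grad_logits(probs, y, cfg$beta,
                                        cfg$class_weights)
        unet_backprop(model, dlogits)
        bcount <- bcount + 1L
        if (bcount == cfg$batch_size || t == length(ord)) {
          step <- step + 1L
          adam_step(layers, cfg$learning_rate, step, scale = bcount)
          nn_zero_grads(layers)
          bcount <- 0L
        }
      }
      history[nrow(history) + 1L, ] <- c(ep, ep_loss / length(ord))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f", ep, ep_loss / length(ord)))
      }
    }
  })
  model$history <- history
  model
}

# Gradient of seg_loss w.r.t. the two-class logits, given softmax probs
# (h, w, 2) and the binary vessel label matrix.
seg_loss_grad_logits <- function(probs, y, beta, class_weights,
                                 eps = 1e-7) {
  d <- dim(probs)
  n <- d[1] * d[2]
  p <- matrix(probs, n, 2)
  yv <- as.numeric(y)
  w <- ifelse(yv > 0.5, class_weights[2], class_weights[1])
  # weighted CE on softmax: dCE/dlogit = w * (p - onehot) / n
  oh <- cbind(1 - yv, yv)
  dce <- w * (p - oh) / n
  # soft Dice on the vessel probability: D = 2*sum(p1*y) / (sum(p1)+sum(y))
  p1 <- p[, 2]
  denom <- sum(p1) + sum(yv) + eps
  num <- 2 * sum(p1 * yv)
  dD_dp1 <- (2 * yv * denom - num) / denom^2
  # loss term is beta * (1 - D); through softmax:
  # dp1/dlogit2 = p1(1-p1), dp1/dlogit1 = -p1*p2 = -(p1(1-p1))
  dp <- p1 * (1 - p1)
  ddice <- -beta * dD_dp1 * dp
  dlog <- dce + cbind(-ddice, ddice)
  array(dlog, d)
}

# Full backward pass through the U-Net graph (head -> decoders -> ups ->
# bottleneck -> pools -> encoders), accumulating skip gradients.
unet_backprop <- function(model, dlogits) {
  d <- model$config$depth
  g <- nn_backward(model$head, dlogits)
  gskips <- vector("list", d - 1L)
  # decoder ran for i = d-1, ..., 1; reverse it
  for (i in seq_len(d - 1L)) {
    g <- nn_backward(model$dec[[i]], g)
    nch <- dim(g)[3]
    half <- nch %/% 2L
    gskips[[i]] <- g[, , seq_len(half), drop = FALSE]
    g <- nn_backward(model$ups[[i]], g[, , half + seq_len(nch - half),
                                       drop = FALSE])
  }
  g <- nn_backward(model$bottleneck, g)
  # encoder ran for i = 1, ..., d-1; reverse it, joining skip gradients
  for (i in rev(seq_len(d - 1L))) {
    g <- nn_backward(model$pools[[i]], g)
    g <- g + gskips[[i]]
    g <- nn_backward(model$enc[[i]], g)
  }
  invisible(g)
}

#' Monte-Carlo dropout prediction stack
#'
#' Runs `n` stochastic forward passes with dropout active at inference;
#' the same seed reproduces the same stack bit-identically.
#'
#' @param image Input image matrix.
#' @param model A trained `unet_model` with `dropout_p > 0`.
#' @param n Number of samples (>= 2).
#' @param seed Integer seed for the dropout masks.
#' @return An h x w x 2 x n array of class probabilities.
#' @export
mc_predict <- function(image, model, n = model$config$n_mc, seed = 1L) {
  if (model$config$dropout_p <= 0) {
    stop("dropout_p is 0: epistemic uncertainty is undefined without ",
         "stochastic forward passes", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 Monte-Carlo samples", call. = FALSE)
  stack <- array(0, c(nrow(image), ncol(image), 2L, n))
  nn_set_mc(model[c("enc", "bottleneck", "ups", "dec")], TRUE)
  on.exit(nn_set_mc(model[c("enc", "bottleneck", "ups", "dec")], FALSE))
  with_seed(seed, {
    for (i in seq_len(n)) {
      stack[, , , i] <- unet_forward(model, image, training = FALSE)
    }
  })
  stack
}

#' Deterministic vessel segmentation (dropout off)
#'
#' @param image Input image matrix.
#' @param model A trained `unet_model`.
#' @return Matrix of vessel-class probabilities.
#' @export
unet_predict <- function(image, model) {
  probs <- unet_forward(model, image, training = FALSE)
  matrix(probs[, , 2], nrow(image), ncol(image))
}

#' Epistemic uncertainty map from a Monte-Carlo prediction stack
#'
#' Per class, the population variance (divide by n) of the n predicted
#' probabilities at each pixel; the map averages the per-class variances
#' over the two classes. Zero exactly where all samples agree; bounded
#' above by 0.25 for probabilities in `[0, 1]`.
#'
#' @param stack h x w x 2 x n array from [mc_predict()].
#' @return h x w matrix of uncertainties.
#' @export
epistemic_uncertainty <- function(stack) {
  d <- dim(stack)
  if (length(d) != 4L || d[4] < 2L) {
    stop("need a stack of at least 2 predictions", call. = FALSE)
  }
  n <- d[4]
  u <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) {
    pk <- array(stack[, , k, ], c(d[1], d[2], n))
    # shift by the first sample: variance is translation-invariant and
    # identical samples then give an exact zero
    pk <- pk - as.vector(pk[, , 1])
    mu <- rowMeans(pk, dims = 2)
    sig2 <- rowMeans(pk^2, dims = 2) - mu^2
    u <- u + pmax(sig2, 0)
  }
  u / d[3]
}
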