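# Vector-quantized variational autoencoder over healthy en face images.
#
# The encoder compresses an image into an h x w grid of d-dimensional
# feature vectors; each vector is replaced by its nearest codebook
# prototype (Euclidean), giving a discrete latent grid. Training minimises
# L1 reconstruction + codebook alignment + commitment losses: the
# alignment term moves only codebook vectors toward encoder outputs (its
# gradient stops at the encoder), the commitment term moves only the
# encoder (gradient stops at the codebook), and reconstruction gradients
# pass straight through the quantizer. The per-position squared distance
# to the selected prototype is the Alignment Loss Map (ALM): large where
# an image looks unlike the healthy training data.

#' VQ-VAE configuration
#'
#' The `desk` preset trains a small model on 128-px phantoms (downsampling
#' factor 8, 16 x 16 latent grid, K = 32 codes of dimension 64); the
#' `paper` preset mirrors the full-scale setting (480-px inputs, 60 x 60
#' latents, K = 128 codes of dimension 256, five convolutional blocks of
#' four residual blocks, 200 epochs) and is reachable but intended for
#' far larger compute budgets.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param image_size Input side length; must be divisible by the total
#'   downsampling factor (8).
#' @param conv_channels Channel widths of the strided convolution blocks.
#' @param strides Stride per convolution block (product = downsampling).
#' @param residual_per_block Residual blocks after each convolution block.
#' @param codebook_k Number of codebook prototype vectors K.
#' @param codebook_dim Dimension d of each prototype.
#' @param dropout_p Dropout probability inside residual blocks.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param warmup_epochs Initial epochs trained as a plain autoencoder
#'   (encoder output fed to the decoder unquantized); afterwards the
#'   codebook is initialised by k-means over encoder features and
#'   quantized training proceeds. The warm-up lets the encoder learn
#'   informative features before the discrete bottleneck is locked in.
#' @param batch_size Gradient-accumulation batch size (the desk preset
#'   uses 1: with a small training set, more optimiser steps matter more
#'   than gradient smoothing).
#' @param commitment_weight Weight of the commitment term (default
#'   0.25: strong enough to keep the encoder committed to its codes,
#'   weak enough not to freeze it against a still-moving codebook).
#' @param codebook_lr_mult Multiplier on the learning rate of the
#'   codebook vectors (the codebook must track the moving encoder, so it
#'   learns faster than the networks).
#' @param reseed_dead_codes Re-seed codebook vectors that went unselected
#'   during an epoch to the features they quantize worst (highest
#'   quantization error), keeping the whole codebook in use; off by
#'   default (dead codes are left untouched).
#' @param augment Character vector among `"hflip"`, `"rot90"`; applied
#'   randomly during training.
#' @param rng_seed Integer seed controlling initialisation, shuffling,
#'   dropout and augmentation.
#' @return An object of class `vqvae_config`.
#' @export
vqvae_config <- function(preset = c("desk", "paper"),
                         image_size = NULL,
                         conv_channels = NULL,
                         strides = NULL,
                         residual_per_block = NULL,
                         codebook_k = NULL,
                         codebook_dim = NULL,
                         dropout_p = 0.1,
                         learning_rate = NULL,
                         epochs = NULL,
                         warmup_epochs = NULL,
                         batch_size = NULL,
                         commitment_weight = 0.25,
                         codebook_lr_mult = 10,
                         reseed_dead_codes = FALSE,
                         augment = c("hflip", "rot90"),
                         rng_seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "desk") {
    list(image_size = 128L, conv_channels = c(8L, 16L, 32L),
         strides = c(2L, 2L, 2L), residual_per_block = 1L,
         codebook_k = 32L, codebook_dim = 64L,
         learning_rate = 1e-3, epochs = 20L, batch_size = 1L,
         warmup_epochs = 5L)
  } else {
    list(image_size = 480L, conv_channels = c(32L, 64L, 128L, 128L, 128L),
         strides = c(2L, 2L, 2L, 1L, 1L), residual_per_block = 4L,
         codebook_k = 128L, codebook_dim = 256L,
         learning_rate = 1e-4, epochs = 200L, batch_size = 4L,
         warmup_epochs = 10L)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(
    preset = preset,
    image_size = as.integer(pick(image_size, def$image_size)),
    conv_channels = as.integer(pick(conv_channels, def$conv_channels)),
    strides = as.integer(pick(strides, def$strides)),
    residual_per_block = as.integer(pick(residual_per_block,
                                         def$residual_per_block)),
    codebook_k = as.integer(pick(codebook_k, def$codebook_k)),
    codebook_dim = as.integer(pick(codebook_dim, def$codebook_dim)),
    dropout_p = dropout_p,
    learning_rate = pick(learning_rate, def$learning_rate),
    epochs = as.integer(pick(epochs, def$epochs)),
    warmup_epochs = as.integer(pick(warmup_epochs,
      min(def$warmup_epochs, max(0L, pick(epochs, def$epochs) - 1L)))),
    batch_size = as.integer(pick(batch_size, def$batch_size)),
    commitment_weight = commitment_weight,
    codebook_lr_mult = codebook_lr_mult,
    reseed_dead_codes = isTRUE(reseed_dead_codes),
    augment = augment,
    rng_seed = as.integer(rng_seed))
  stopifnot(cfg$codebook_k >= 2, length(cfg$conv_channels) ==
              length(cfg$strides), cfg$learning_rate > 0, cfg$epochs >= 1,
            cfg$warmup_epochs >= 0, cfg$warmup_epochs < cfg$epochs)
  cfg$downsample <- prod(cfg$strides)
  if (cfg$image_size %% cfg$downsample != 0) {
    stop("image_size must be divisible by the downsampling factor ",
         cfg$downsample, call. = FALSE)
  }
  structure(cfg, class = "vqvae_config")
}

res_block <- function(ch, dropout_p) {
  nn_residual(nn_relu(), nn_conv(ch, ch, 3), nn_relu(),
              nn_conv(ch, ch, 1), nn_dropout(dropout_p))
}

#' Build an untrained VQ-VAE model
#'
#' @param cfg A [vqvae_config()].
#' @return A `vqvae_model` list with `encoder`, `decoder`, `codebook`
#'   (a K x d matrix) and the config.
#' @export
vqvae_model <- function(cfg) {
  stopifnot(inherits(cfg, "vqvae_config"))
  with_seed(cfg$rng_seed, {
    ch <- cfg$conv_channels
    n <- length(ch)
    enc <- list()
    cin <- 1L
    for (i in seq_len(n)) {
      k <- if (cfg$strides[i] == 2L) 4L else 3L
      enc[[length(enc) + 1L]] <- nn_conv(cin, ch[i], k,
                                         stride = cfg$strides[i], pad = 1L)
      enc[[length(enc) + 1L]] <- nn_relu()
      for (r in seq_len(cfg$residual_per_block)) {
        enc[[length(enc) + 1L]] <- res_block(ch[i], cfg$dropout_p)
      }
      cin <- ch[i]
    }
    proj <- nn_conv(cin, cfg$codebook_dim, 1, pad = 0L)
    proj$W <- proj$W / 4   # moderate feature scale stabilises quantization
    enc[[length(enc) + 1L]] <- proj
    encoder <- nn_sequential(enc)

    dec <- list(nn_conv(cfg$codebook_dim, ch[n], 1, pad = 0L))
    for (r in seq_len(cfg$residual_per_block)) {
      dec[[length(dec) + 1L]] <- res_block(ch[n], cfg$dropout_p)
    }
    for (i in rev(seq_len(n))) {
      cout <- if (i > 1) ch[i - 1] else max(8L, ch[1] %/% 2L)
      if (cfg$strides[i] == 2L) {
        dec[[length(dec) + 1L]] <- nn_tconv2(ch[i], cout)
      } else {
        dec[[length(dec) + 1L]] <- nn_conv(ch[i], cout, 3)
      }
      dec[[length(dec) + 1L]] <- nn_relu()
      if (i > 1) ch[i - 1] <- cout
    }
    last_ch <- max(8L, cfg$conv_channels[1] %/% 2L)
    dec[[length(dec) + 1L]] <- nn_conv(last_ch, 1, 3)
    decoder <- nn_sequential(dec)

    codebook <- new_layer("nn_codebook",
      vectors = matrix(stats::rnorm(cfg$codebook_k * cfg$codebook_dim,
                                    sd = 0.5),
                       cfg$codebook_k, cfg$codebook_dim),
      param_names = "vectors")
    structure(list(encoder = encoder, decoder = decoder,
                   codebook = codebook, config = cfg),
              class = "vqvae_model")
  })
}

#' Encode an image into the feature grid
#'
#' Runs the encoder in inference mode (dropout off).
#'
#' @param image Numeric matrix; side lengths must be divisible by the
#'   model's downsampling factor.
#' @param model A `vqvae_model`.
#' @return An h x w x d feature array.
#' @export
vqvae_encode <- function(image, model) {
  ds <- model$config$downsample
  if (nrow(image) %% ds != 0 || ncol(image) %% ds != 0) {
    stop("image sides must be divisible by the downsampling factor ", ds,
         call. = FALSE)
  }
  nn_forward(model$encoder, as_hwc(image), training = FALSE)
}

#' Quantize a feature grid against a codebook
#'
#' Each d-dimensional feature vector is replaced by its nearest codebook
#' prototype in Euclidean distance (distance ties broken by lowest
#' index). The Alignment Loss Map holds the squared distance to the
#' selected prototype.
#'
#' @param features h x w x d feature array (or N x d matrix).
#' @param codebook K x d numeric matrix of prototype vectors.
#' @return A list with `indices` (h x w integer matrix, 1-based),
#'   `quantized` (h x w x d array) and `alm` (h x w matrix).
#' @export
quantize <- function(features, codebook) {
  if (inherits(codebook, "nn_layer")) codebook <- codebook$vectors
  dims <- dim(features)
  is_grid <- length(dims) == 3L
  fm <- if (is_grid) matrix(features, dims[1] * dims[2], dims[3]) else
    as.matrix(features)
  h <- if (is_grid) dims[1] else nrow(fm)
  w <- if (is_grid) dims[2] else 1L
  if (ncol(fm) != ncol(codebook)) {
    stop("feature dimension (", ncol(fm), ") does not match codebook (",
         ncol(codebook), ")", call. = FALSE)
  }
  # ||f - e||^2 = ||f||^2 - 2 f.e + ||e||^2 ; argmin with first-index ties
  cross <- fm %*% t(codebook)
  e2 <- rowSums(codebook^2)
  dist2 <- sweep(-2 * cross, 2, e2, `+`) + rowSums(fm^2)
  # guard against tiny negative round-off breaking exact-zero ALM cells
  idx <- max.col(-dist2, ties.method = "first")
  q <- codebook[idx, , drop = FALSE]
  alm <- rowSums((fm - q)^2)
  list(indices = matrix(idx, h, w),
       quantized = if (is_grid) array(q, dims) else q,
       alm = matrix(alm, h, w))
}

#' Decode a quantized feature grid
#'
#' @param quantized h x w x d array of codebook vectors.
#' @param model A `vqvae_model`.
#' @return Reconstructed image matrix at input resolution.
#' @export
vqvae_decode <- function(quantized, model) {
  if (dim(as_hwc(quantized))[3] != model$config$codebook_dim) {
    stop("quantized grid depth does not match the decoder", call. = FALSE)
  }
  out <- nn_forward(model$decoder, quantized, training = FALSE)
  matrix(out, dim(out)[1], dim(out)[2])
}

#' VQ-VAE loss components
#'
#' Reconstruction is the mean absolute error; alignment and commitment
#' are the mean (over latent positions) squared distances between encoder
#' features and their selected codebook vectors. The two distances are
#' numerically equal - they differ only in which side receives the
#' gradient during training (alignment updates the codebook, commitment
#' the encoder).
#'
#' @param x,x_prime Input and reconstructed image matrices.
#' @param features,quantized h x w x d arrays.
#' @param codebook K x d matrix (unused beyond shape checks; kept for a
#'   complete signature).
#' @param commitment_weight Weight applied to the commitment term in the
#'   total.
#' @return A list with `reconstruction`, `alignment`, `commitment`,
#'   `total`.
#' @export
vqvae_loss <- function(x, x_prime, features, quantized, codebook = NULL,
                       commitment_weight = 1.0) {
  if (!identical(dim(x), dim(x_prime))) {
    stop("x and x_prime shapes differ", call. = FALSE)
  }
  if (!identical(dim(features), dim(quantized))) {
    stop("features and quantized shapes differ", call. = FALSE)
  }
  d <- dim(as_hwc(features))
  ncell <- d[1] * d[2]
  recon <- mean(abs(x - x_prime))
  sq <- sum((features - quantized)^2) / ncell
  list(reconstruction = recon, alignment = sq, commitment = sq,
       total = recon + sq + commitment_weight * sq)
}

#' Upscale an Alignment Loss Map to image resolution
#'
#' Nearest-neighbour interpolation (values are preserved exactly, so the
#' maximum never increases and constant maps stay constant).
#'
#' @param alm h x w matrix.
#' @param target_size Output side length (>= latent size).
#' @return `target_size` x `target_size` matrix.
#' @export
alignment_loss_map_upscaled <- function(alm, target_size) {
  h <- nrow(alm); w <- ncol(alm)
  stopifnot(target_size >= h, target_size >= w)
  ri <- floor((seq_len(target_size) - 1) * h / target_size) + 1
  ci <- floor((seq_len(target_size) - 1) * w / target_size) + 1
  alm[ri, ci, drop = FALSE]
}

#' Compute the upscaled Alignment Loss Map of an image
#'
#' @param image Standardized image matrix.
#' @param model A trained `vqvae_model`.
#' @param upscale Logical; return the map at image resolution
#'   (nearest-neighbour) rather than latent resolution.
#' @return A nonnegative score-map matrix.
#' @export
alm_map <- function(image, model, upscale = TRUE) {
  f <- vqvae_encode(image, model)
  q <- quantize(f, model$codebook)
  if (upscale) alignment_loss_map_upscaled(q$alm, nrow(image)) else q$alm
}

augment_image <- function(img, augment) {
  if ("hflip" %in% augment && stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(ncol(img)))]
  }
  if ("rot90" %in% augment) {
    k <- sample(0:3, 1)
    for (t in seq_len(k)) img <- t(img[rev(seq_len(nrow(img))), ])
  }
  img
}

load_split_images <- function(manifest, split, label = NULL) {
  sel <- manifest$split %in% split
  if (!is.null(label)) sel <- sel & manifest$label %in% label
  idx <- which(sel)
  lapply(idx, function(i) load_image(manifest_path(manifest, "image", i)))
}

# k-means codebook initialisation over encoder features of (up to) 8
# training images; every prototype starts inside the feature
# distribution, so no code is born dead.
init_codebook <- function(model, images) {
  feats <- lapply(images[seq_len(min(8, length(images)))], function(x) {
    E <- nn_forward(model$encoder, as_hwc(x), training = FALSE)
    matrix(E, prod(dim(E)[1:2]), dim(E)[3])
  })
  feats <- do.call(rbind, feats)
  K <- nrow(model$codebook$vectors)
  centers <- tryCatch(
    suppressWarnings(stats::kmeans(feats, centers = K, iter.max = 25,
                                   nstart = 1))$centers,
    error = function(e) {
      # degenerate feature sets (fewer distinct points than K): sample
      # rows with replacement and jitter
      idx <- sample(nrow(feats), K, replace = TRUE)
      feats[idx, , drop = FALSE] +
        matrix(stats::rnorm(K * ncol(feats), sd = 1e-3), K, ncol(feats))
    })
  model$codebook$vectors <- unname(as.matrix(centers))
  model$codebook$opt <- list()   # fresh optimiser state
  invisible(model)
}

#' Train a VQ-VAE on the healthy training split
#'
#' Refuses to train if any diseased record sits in the train split (the
#' model must only ever see healthy anatomy). Mini-batches accumulate
#' gradients over `batch_size` images before each Adam step.
#'
#' @param manifest Dataset manifest (see [make_dataset()]); alternatively
#'   pass preloaded images via `images`.
#' @param cfg A [vqvae_config()].
#' @param images Optional list of preprocessed image matrices overriding
#'   the manifest's train split.
#' @param verbose Print per-epoch losses.
#' @return A trained `vqvae_model` with a `history` data.frame attached.
#' @export
train_vqvae <- function(manifest, cfg, images = NULL, verbose = FALSE) {
  if (is.null(images)) {
    validate_manifest(manifest)
    tr <- manifest[manifest$split == "train", ]
    if (any(tr$label == "diseased")) {
      stop("train split contains diseased images; unsupervised training ",
           "requires healthy-only data", call. = FALSE)
    }
    if (nrow(tr) == 0) stop("train split is empty", call. = FALSE)
    images <- load_split_images(manifest, "train", "healthy")
  }
  if (length(images) == 0) stop("no training images", call. = FALSE)
  model <- vqvae_model(cfg)
  net_layers <- c(nn_collect(model$encoder), nn_collect(model$decoder))
  layers <- c(net_layers, list(model$codebook))
  cw <- cfg$commitment_weight
  history <- data.frame(epoch = integer(), reconstruction = numeric(),
                        alignment = numeric(), total = numeric())
  with_seed(cfg$rng_seed + 1L, {
    step <- 0L
    quantizing <- cfg$warmup_epochs == 0L
    if (quantizing) init_codebook(model, images)
    for (ep in seq_len(cfg$epochs)) {
      if (!quantizing && ep > cfg$warmup_epochs) {
        init_codebook(model, images)
        quantizing <- TRUE
      }
      ord <- sample(length(images))
      ep_loss <- c(recon = 0, align = 0, total = 0)
      bcount <- 0L
      used <- logical(cfg$codebook_k)
      worst <- list(err = -Inf, feat = NULL)
      nn_zero_grads(layers)
      for (t in seq_along(ord)) {
        x <- augment_image(images[[ord[t]]], cfg$augment)
        E <- nn_forward(model$encoder, as_hwc(x), training = TRUE)
        d <- dim(E)
        ncell <- d[1] * d[2]
        if (quantizing) {
          qz <- quantize(E, model$codebook)
          dec_in <- qz$quantized
          used[unique(as.vector(qz$indices))] <- TRUE
          if (cfg$reseed_dead_codes) {
            wi <- which.max(qz$alm)
            if (qz$alm[wi] > worst$err) {
              worst$err <- qz$alm[wi]
              worst$feat <- matrix(E, ncell, d[3])[wi, ]
            }
          }
        } else {
          dec_in <- E
        }
        xp <- nn_forward(model$decoder, dec_in, training = TRUE)
        xp <- matrix(xp, nrow(x), ncol(x))
        # reconstruction gradient (L1), through decoder
        dxp <- array(sign(xp - x) / length(x), c(dim(x), 1))
        dq <- nn_backward(model$decoder, dxp)
        if (quantizing) {
          loss <- vqvae_loss(x, xp, E, qz$quantized,
                             commitment_weight = cw)
          # straight-through to encoder + commitment pull toward codes
          dE <- dq + cw * 2 * (E - qz$quantized) / ncell
          nn_backward(model$encoder, dE)
          # alignment gradient on selected codebook rows
          fm <- matrix(E, ncell, d[3])
          qm <- matrix(qz$quantized, ncell, d[3])
          dcb <- rowsum(2 * (qm - fm) / ncell,
                        group = as.vector(qz$indices))
          dvec <- matrix(0, nrow(model$codebook$vectors), d[3])
          dvec[as.integer(rownames(dcb)), ] <- dcb
          acc_grad(model$codebook, "vectors", dvec)
        } else {
          loss <- list(reconstruction = mean(abs(x - xp)), alignment = 0,
                       total = mean(abs(x - xp)))
          nn_backward(model$encoder, dq)
        }
        ep_loss <- ep_loss + c(loss$reconstruction, loss$alignment,
                               loss$total)
        bcount <- bcount + 1L
        if (bcount == cfg$batch_size || t == length(ord)) {
          step <- step + 1L
          adam_step(net_layers, cfg$learning_rate, step, scale = bcount)
          if (quantizing) {
            adam_step(list(model$codebook),
                      cfg$learning_rate * cfg$codebook_lr_mult, step,
                      scale = bcount)
          }
          nn_zero_grads(layers)
          bcount <- 0L
        }
      }
      if (quantizing && cfg$reseed_dead_codes && any(!used) &&
          !is.null(worst$feat)) {
        dead <- which(!used)
        for (k in dead) {
          model$codebook$vectors[k, ] <- worst$feat +
            stats::rnorm(d[3], sd = 0.01)
          model$codebook$opt <- list()
        }
      }
      ep_loss <- ep_loss / length(ord)
      history[nrow(history) + 1L, ] <- c(ep, ep_loss["recon"],
                                         ep_loss["align"], ep_loss["total"])
      if (verbose) {
        message(sprintf("epoch %3d%s  recon %.4f  align %.4f  total %.4f",
                        ep, if (quantizing) "" else " (warmup)",
                        ep_loss[1], ep_loss[2], ep_loss[3]))
      }
    }
  })
  model$history <- history
  model
}

#' Save / load a model
#'
#' Models are environments of plain numeric arrays; they serialize with
#' the config embedded.
#'
#' @param model A model object.
#' @param path File path (`.rds`).
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
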