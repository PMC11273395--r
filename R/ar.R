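# Autoregressive prior over the discrete latent grids of healthy images.
#
# The joint distribution of a latent grid factorises over positions in
# raster order (row-major, left-to-right, top-to-bottom): p(z) =
# prod_i p(z_i | z_<i). A masked-convolution network (PixelCNN-style)
# realises the causal conditionals: the first layer uses a type-A mask
# (center excluded), later layers type-B masks (center included), so the
# categorical output at each position depends only on strictly preceding
# positions. Scans are scored by summing per-position negative
# log-likelihood above a calibrated threshold t_ar: anomalous latents are
# improbable under the healthy prior and accumulate surprise.

#' AR prior configuration
#'
#' @param preset `"desk"` (16 x 16 grids, 32 symbols) or `"paper"`
#'   (60 x 60 grids, 128 symbols, 300 epochs).
#' @param codebook_k Number of latent symbols K (must match the VQ-VAE).
#' @param channels Hidden channel width of the masked convolutions.
#' @param n_blocks Number of hidden masked-convolution blocks.
#' @param positional Add two normalised coordinate channels to the
#'   input. The causal conditionals then know *where* on the retina a
#'   configuration sits (the foveal avascular zone is a legitimate
#'   signal void only at the center); coordinates carry no information
#'   about future symbols, so causality is untouched.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param rng_seed Integer seed.
#' @return An object of class `ar_config`.
#' @export
ar_config <- function(preset = c("desk", "paper"),
                      codebook_k = NULL,
                      channels = NULL,
                      n_blocks = NULL,
                      learning_rate = 5e-4,
                      epochs = NULL,
                      batch_size = 4L,
                      positional = TRUE,
                      rng_seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "desk") {
    list(codebook_k = 32L, channels = 32L, n_blocks = 2L, epochs = 80L)
  } else {
    list(codebook_k = 128L, channels = 128L, n_blocks = 4L, epochs = 300L)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(preset = preset,
              codebook_k = as.integer(pick(codebook_k, def$codebook_k)),
              channels = as.integer(pick(channels, def$channels)),
              n_blocks = as.integer(pick(n_blocks, def$n_blocks)),
              learning_rate = learning_rate,
              epochs = as.integer(pick(epochs, def$epochs)),
              batch_size = as.integer(batch_size),
              positional = isTRUE(positional),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$codebook_k >= 2, cfg$channels >= 1, cfg$epochs >= 1,
            learning_rate > 0)
  structure(cfg, class = "ar_config")
}

# Weight mask enforcing raster-order causality for a k x k convolution
# with cin inputs and cout outputs. Type "A" excludes the center weight
# (first layer), type "B" includes it. Row ordering matches nn_conv
# weights: (ki, kj, c) with ki fastest.
causal_mask <- function(k, cin, cout, type = c("B", "A")) {
  type <- match.arg(type)
  ctr <- (k + 1L) %/% 2L
  pos <- matrix(0, k, k)
  pos[seq_len(ctr - 1L), ] <- 1        # rows above the center: all columns
  pos[ctr, seq_len(ctr - 1L)] <- 1     # same row, strictly to the left
  if (type == "B") pos[ctr, ctr] <- 1
  matrix(rep(as.vector(pos), cin), k * k * cin, cout)
}

masked_conv <- function(cin, cout, k, type) {
  nn_conv(cin, cout, k, mask = causal_mask(k, cin, cout, type))
}

#' Build an untrained AR prior model
#'
#' @param cfg An [ar_config()].
#' @return An `ar_model` list with the causal network and config.
#' @export
ar_model <- function(cfg) {
  stopifnot(inherits(cfg, "ar_config"))
  with_seed(cfg$rng_seed, {
    K <- cfg$codebook_k
    cin <- K + if (cfg$positional) 2L else 0L
    ch <- cfg$channels
    net <- list(masked_conv(cin, ch, 5, "A"), nn_relu())
    for (b in seq_len(cfg$n_blocks)) {
      net[[length(net) + 1L]] <- masked_conv(ch, ch, 3, "B")
      net[[length(net) + 1L]] <- nn_relu()
    }
    net[[length(net) + 1L]] <- masked_conv(ch, ch, 1, "B")
    net[[length(net) + 1L]] <- nn_relu()
    net[[length(net) + 1L]] <- masked_conv(ch, K, 1, "B")
    structure(list(net = nn_sequential(net), config = cfg),
              class = "ar_model")
  })
}

one_hot_grid <- function(latents, K, positional = FALSE) {
  if (any(latents < 1L | latents > K)) {
    stop("latent indices must lie in 1..K", call. = FALSE)
  }
  h <- nrow(latents); w <- ncol(latents)
  oh <- array(0, c(h, w, K + if (positional) 2L else 0L))
  oh[cbind(rep(seq_len(h), w), rep(seq_len(w), each = h),
           as.vector(latents))] <- 1
  if (positional) {
    oh[, , K + 1L] <- matrix((seq_len(h) - 1) / max(1, h - 1), h, w)
    oh[, , K + 2L] <- matrix((seq_len(w) - 1) / max(1, w - 1), h, w,
                             byrow = TRUE)
  }
  oh
}

# Stable per-cell log-softmax of an (h, w, K) logit array.
log_softmax_grid <- function(logits) {
  d <- dim(logits)
  lm <- matrix(logits, d[1] * d[2], d[3])
  mx <- as.numeric(Reduce(pmax, asplit(lm, 2)))
  ls <- lm - mx - log(rowSums(exp(lm - mx)))
  array(ls, d)
}

#' Per-position negative log-likelihood map
#'
#' Runs the causal network once; the NLL at each position is the
#' categorical surprise of the observed symbol under the conditional
#' distribution given its raster-order predecessors. Cells sum to
#' `-log p(z)` of the whole grid.
#'
#' @param latents h x w integer matrix of 1-based symbol indices.
#' @param model An `ar_model`.
#' @return h x w matrix of nonnegative NLL values (nats).
#' @export
nll_map <- function(latents, model) {
  K <- model$config$codebook_k
  oh <- one_hot_grid(latents, K, model$config$positional)
  logits <- nn_forward(model$net, oh, training = FALSE)
  ls <- log_softmax_grid(logits)
  h <- nrow(latents); w <- ncol(latents)
  picked <- ls[cbind(rep(seq_len(h), w), rep(seq_len(w), each = h),
                     as.vector(latents))]
  matrix(-picked, h, w)
}

#' Scan-wise anomaly score from an NLL map
#'
#' Sum of NLL cells strictly above the threshold `t_ar`; zero when no
#' cell exceeds it.
#'
#' @param nll Matrix of nonnegative NLL values.
#' @param t_ar Nonnegative threshold (nats).
#' @return A single nonnegative number.
#' @export
scan_score <- function(nll, t_ar) {
  stopifnot(t_ar >= 0)
  sum(nll[nll > t_ar])
}

#' Calibrate the scan-score threshold on validation NLL values
#'
#' Returns the given percentile (linear-interpolation convention) of the
#' pooled per-cell validation NLL values of healthy scans, following the
#' practice of choosing t_ar as the 95th percentile on the validation
#' set.
#'
#' @param validation_nll_values Numeric vector of pooled NLL cells.
#' @param percentile Percentile in `[0, 100]` (default 95).
#' @return The threshold as a single number.
#' @export
calibrate_t_ar <- function(validation_nll_values, percentile = 95) {
  if (length(validation_nll_values) == 0) {
    stop("validation NLL collection is empty", call. = FALSE)
  }
  unname(stats::quantile(validation_nll_values, percentile / 100,
                         type = 7, names = FALSE))
}

#' Train the AR prior on healthy latent grids
#'
#' Minimises per-position categorical cross-entropy (equivalently the
#' mean NLL) with Adam.
#'
#' With a small healthy cohort the prior can overfit: held-out healthy
#' grids then look increasingly surprising, which erodes the contrast
#' with truly anomalous grids. When validation latents are supplied the
#' trainer therefore monitors their mean NLL and keeps the weights of
#' the best validation epoch (early stopping with the given patience).
#'
#' @param latent_dataset List of h x w integer matrices produced by a
#'   frozen trained VQ-VAE on the healthy train split.
#' @param cfg An [ar_config()].
#' @param val_latents Optional list of healthy validation latent grids
#'   used for early stopping.
#' @param patience Epochs without validation improvement before
#'   stopping (when `val_latents` is given).
#' @param verbose Print per-epoch mean NLL.
#' @return A trained `ar_model` with a `history` data.frame attached.
#' @export
train_ar <- function(latent_dataset, cfg, val_latents = NULL,
                     patience = 5L, verbose = FALSE) {
  if (length(latent_dataset) == 0) stop("empty latent dataset",
                                        call. = FALSE)
  model <- ar_model(cfg)
  layers <- nn_collect(model$net)
  K <- cfg$codebook_k
  history <- data.frame(epoch = integer(), nll = numeric(),
                        val_nll = numeric())
  best <- list(val = Inf, params = NULL, wait = 0L)
  snapshot <- function() lapply(layers, function(l) {
    stats::setNames(lapply(l$param_names, function(nm) l[[nm]]),
                    l$param_names)
  })
  with_seed(cfg$rng_seed + 1L, {
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(latent_dataset))
      ep_nll <- 0
      bcount <- 0L
      nn_zero_grads(layers)
      for (t in seq_along(ord)) {
        z <- latent_dataset[[ord[t]]]
        oh <- one_hot_grid(z, K, cfg$positional)
        target <- if (cfg$positional) oh[, , seq_len(K), drop = FALSE]
                  else oh
        logits <- nn_forward(model$net, oh, training = TRUE)
        d <- dim(logits)
        ncell <- d[1] * d[2]
        ls <- log_softmax_grid(logits)
        probs <- exp(ls)
        ep_nll <- ep_nll - sum(ls * target) / ncell
        dlogits <- (probs - target) / ncell
        nn_backward(model$net, dlogits)
        bcount <- bcount + 1L
        if (bcount == cfg$batch_size || t == length(ord)) {
          step <- step + 1L
          adam_step(layers, cfg$learning_rate, step, scale = bcount)
          nn_zero_grads(layers)
          bcount <- 0L
        }
      }
      val_nll <- NA_real_
      if (!is.null(val_latents) && length(val_latents) > 0) {
        val_nll <- mean(vapply(val_latents, function(z)
          mean(nll_map(z, model)), numeric(1)))
        if (val_nll < best$val - 1e-6) {
          best$val <- val_nll
          best$params <- snapshot()
          best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
        }
      }
      history[nrow(history) + 1L, ] <- c(ep, ep_nll / length(ord),
                                         val_nll)
      if (verbose) {
        message(sprintf("epoch %3d  nll/cell %.4f  val %.4f", ep,
                        ep_nll / length(ord), val_nll))
      }
      if (!is.null(best$params) && best$wait >= patience) break
    }
  })
  if (!is.null(best$params)) {   # restore the best-validation weights
    for (i in seq_along(layers)) {
      for (nm in layers[[i]]$param_names) {
        layers[[i]][[nm]] <- best$params[[i]][[nm]]
      }
    }
  }
  model$history <- history
  model
}
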