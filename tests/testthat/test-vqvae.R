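# VQ-VAE: quantization semantics, loss arithmetic, ALM behaviour and
# training contracts.

test_that("quantize matches exhaustive nearest-neighbour search", {
  set.seed(1)
  for (rep in 1:20) {
    K <- sample(2:16, 1); d <- sample(2:8, 1)
    cb <- matrix(rnorm(K * d), K, d)
    f <- array(rnorm(4 * 5 * d), c(4, 5, d))
    q <- quantize(f, cb)
    fm <- matrix(f, 20, d)
    for (i in seq_len(20)) {
      dist2 <- colSums((t(cb) - fm[i, ])^2)
      expect_identical(q$indices[i], which.min(dist2))
      expect_equal(q$alm[i], min(dist2), tolerance = 1e-12)
    }
  }
})

test_that("quantize handles exact matches, ties and mismatches", {
  cb <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  # feature (0.1, 0.1): distance 0.02 to code 1, 1.62 to code 2
  q <- quantize(array(c(0.1, 0.1), c(1, 1, 2)), cb)
  expect_identical(q$indices[1, 1], 1L)
  expect_equal(q$alm[1, 1], 0.02)
  # exact codebook vector: ALM exactly zero
  q2 <- quantize(array(cb[2, ], c(1, 1, 2)), cb)
  expect_identical(q2$indices[1, 1], 2L)
  expect_identical(q2$alm[1, 1], 0)
  # equidistant: lowest index wins
  q3 <- quantize(array(c(0.5, 0.5), c(1, 1, 2)), cb)
  expect_identical(q3$indices[1, 1], 1L)
  expect_error(quantize(array(0, c(1, 1, 3)), cb), "dimension")
})

test_that("quantize is idempotent on quantized grids", {
  set.seed(2)
  cb <- matrix(rnorm(8 * 4), 8, 4)
  f <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  q1 <- quantize(f, cb)
  q2 <- quantize(q1$quantized, cb)
  expect_identical(q1$indices, q2$indices)
  expect_true(all(q2$alm == 0))
})

test_that("encoder produces the configured latent geometry", {
  cfg <- vqvae_config("desk", rng_seed = 7)
  m <- vqvae_model(cfg)
  x <- matrix(runif(128 * 128), 128, 128)
  E <- vqvae_encode(x, m)
  expect_equal(dim(E), c(16, 16, cfg$codebook_dim))
  expect_error(vqvae_encode(matrix(0, 100, 100), m), "divisible")
  # deterministic inference
  expect_identical(E, vqvae_encode(x, m))
  # the 8x downsampling ratio maps 480-px inputs to 60x60 latents
  cfg2 <- vqvae_config("desk", image_size = 480L,
                       conv_channels = c(2L, 2L, 2L),
                       codebook_dim = 4L, rng_seed = 1)
  m2 <- vqvae_model(cfg2)
  E2 <- vqvae_encode(matrix(runif(480 * 480), 480, 480), m2)
  expect_equal(dim(E2)[1:2], c(60, 60))
})

test_that("decoder restores the input resolution deterministically", {
  cfg <- vqvae_config("desk", rng_seed = 8)
  m <- vqvae_model(cfg)
  x <- matrix(runif(128 * 128), 128, 128)
  q <- quantize(vqvae_encode(x, m), m$codebook)
  xp <- vqvae_decode(q$quantized, m)
  expect_equal(dim(xp), dim(x))
  expect_identical(xp, vqvae_decode(q$quantized, m))
  expect_error(vqvae_decode(array(0, c(16, 16, 3)), m), "decoder")
})

test_that("vqvae_loss components match direct arithmetic", {
  set.seed(3)
  x <- matrix(runif(16), 4, 4)
  xp <- matrix(runif(16), 4, 4)
  f <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  q <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  loss <- vqvae_loss(x, xp, f, q, commitment_weight = 0.7)
  expect_equal(loss$reconstruction, mean(abs(x - xp)), tolerance = 1e-12)
  sq <- sum((f - q)^2) / 4
  expect_equal(loss$alignment, sq, tolerance = 1e-12)
  expect_equal(loss$commitment, sq, tolerance = 1e-12)
  expect_equal(loss$total, loss$reconstruction + sq + 0.7 * sq,
               tolerance = 1e-12)
  # alignment and commitment are the same number (they differ only in
  # gradient routing)
  expect_identical(loss$alignment, loss$commitment)
  # perfect reconstruction with features on their codes: all zeros
  z <- vqvae_loss(x, x, q, q)
  expect_equal(z$total, 0)
  expect_error(vqvae_loss(x, xp[1:2, ], f, q), "shapes")
})

test_that("ALM upscaling is nearest-neighbour and order preserving", {
  alm <- matrix(c(1, 2, 3, 4), 2, 2)
  up <- alignment_loss_map_upscaled(alm, 4)
  expect_equal(up, alm[c(1, 1, 2, 2), c(1, 1, 2, 2)])
  # constants stay constant
  expect_true(all(alignment_loss_map_upscaled(matrix(0.3, 2, 2), 8)
                  == 0.3))
  # max never increases
  set.seed(4)
  for (t in 1:10) {
    a <- matrix(rexp(16), 4, 4)
    expect_lte(max(alignment_loss_map_upscaled(a, 9)), max(a))
  }
})

test_that("training refuses diseased images in the train split", {
  man <- data.frame(image = c("a.png", "b.png"),
                    vessel_mask = c("", ""),
                    anomaly_mask = c("", "m.png"),
                    label = c("healthy", "diseased"),
                    split = c("train", "train"))
  expect_error(train_vqvae(man, vqvae_config("desk")), "train split")
})

test_that("desk-scale training runs and its loss decreases", {
  phs <- tiny_phantoms(6, size = 32)
  imgs <- lapply(phs, `[[`, "image")
  cfg <- vqvae_config("desk", image_size = 32L, epochs = 12,
                      rng_seed = 5)
  m <- train_vqvae(NULL, cfg, images = imgs)
  expect_true(all(is.finite(m$history$total)))
  # smoothed early vs late loss
  expect_lt(mean(tail(m$history$total, 3)), mean(head(m$history$total, 3)))
  # reconstruction of a training image has sane scale
  xp <- vqvae_decode(quantize(vqvae_encode(imgs[[1]], m),
                              m$codebook)$quantized, m)
  expect_true(all(is.finite(xp)))
})

test_that("training on constant images reconstructs their mean", {
  imgs <- replicate(4, matrix(0.6, 32, 32), simplify = FALSE)
  cfg <- vqvae_config("desk", image_size = 32L, epochs = 80,
                      batch_size = 1L, learning_rate = 1e-3,
                      augment = character(), rng_seed = 6)
  m <- train_vqvae(NULL, cfg, images = imgs)
  xp <- vqvae_decode(quantize(vqvae_encode(imgs[[1]], m),
                              m$codebook)$quantized, m)
  expect_lt(abs(mean(xp) - 0.6), 0.1)
})
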