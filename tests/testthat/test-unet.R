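# Bayesian U-Net: loss arithmetic, Monte-Carlo dropout and epistemic
# uncertainty.

test_that("seg_loss matches hand-computed CE + beta * (1 - Dice)", {
  set.seed(1)
  p <- matrix(runif(64), 8, 8)
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  beta <- 0.6
  got <- seg_loss(p, y, beta)
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  ce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dsc <- 2 * sum(pc * y) / (sum(pc) + sum(y) + eps)
  expect_equal(got, ce + beta * (1 - dsc), tolerance = 1e-6)
  # beta = 0 removes the Dice term
  expect_equal(seg_loss(p, y, 0), ce, tolerance = 1e-6)
  # near-perfect prediction: loss near zero
  expect_lt(seg_loss(y, y), 1e-5)
  expect_error(seg_loss(p, y[1:4, ]), "shapes")
})

test_that("unet forward yields valid probabilities at input size", {
  cfg <- unet_config("desk", depth = 3, base_channels = 4, rng_seed = 2)
  m <- unet_model(cfg)
  x <- matrix(runif(32 * 32), 32, 32)
  probs <- unet_forward(m, x)
  expect_equal(dim(probs), c(32, 32, 2))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(max(abs(probs[, , 1] + probs[, , 2] - 1)), 0,
               tolerance = 1e-12)
  # dropout off: repeated inference is identical
  expect_identical(unet_predict(x, m), unet_predict(x, m))
})

test_that("mc_predict is seeded and requires active dropout", {
  cfg <- unet_config("desk", depth = 3, base_channels = 4,
                     dropout_p = 0.2, rng_seed = 3)
  m <- unet_model(cfg)
  x <- matrix(runif(16 * 16), 16, 16)
  s1 <- mc_predict(x, m, n = 4, seed = 11)
  s2 <- mc_predict(x, m, n = 4, seed = 11)
  expect_identical(s1, s2)
  expect_false(identical(s1, mc_predict(x, m, n = 4, seed = 12)))
  expect_equal(dim(s1), c(16, 16, 2, 4))
  expect_error(mc_predict(x, m, n = 1, seed = 1), "at least 2")
  m0 <- unet_model(unet_config("desk", depth = 3, base_channels = 4,
                               dropout_p = 0, rng_seed = 3))
  expect_error(mc_predict(x, m0, n = 4, seed = 1), "dropout_p")
})

test_that("epistemic uncertainty equals the population variance", {
  set.seed(4)
  n <- 7
  stack <- array(runif(6 * 5 * 2 * n), c(6, 5, 2, n))
  stack[, , 2, ] <- 1 - stack[, , 1, ]  # complementary classes
  u <- epistemic_uncertainty(stack)
  # independent two-pass oracle
  for (t in 1:15) {
    i <- sample(6, 1); j <- sample(5, 1)
    v <- 0
    for (k in 1:2) {
      y <- stack[i, j, k, ]
      v <- v + mean((y - mean(y))^2)
    }
    expect_equal(u[i, j], v / 2, tolerance = 1e-9)
  }
  # complementary classes have equal variance: u equals either one
  y1 <- stack[2, 2, 1, ]
  expect_equal(u[2, 2], mean((y1 - mean(y1))^2), tolerance = 1e-12)
  # bounded by 1/4 for [0,1] probabilities
  expect_true(all(u >= 0 & u <= 0.25))
})

test_that("uncertainty closed forms hold exactly", {
  # identical predictions: u identically zero
  one <- array(runif(4 * 4 * 2), c(4, 4, 2))
  stack <- array(rep(one, 5), c(4, 4, 2, 5))
  expect_true(all(epistemic_uncertainty(stack) == 0))
  # two samples with class probabilities {0,1}: mu = 1/2, sigma^2 = 1/4
  st <- array(0, c(1, 1, 2, 2))
  st[1, 1, , 1] <- c(1, 0)
  st[1, 1, , 2] <- c(0, 1)
  expect_equal(epistemic_uncertainty(st)[1, 1], 0.25)
  expect_error(epistemic_uncertainty(array(0, c(2, 2, 2, 1))),
               "at least 2")
})

test_that("training contracts: missing masks refused, smoke run finite", {
  man <- data.frame(image = "a.png", vessel_mask = "",
                    anomaly_mask = "", label = "healthy",
                    split = "train")
  expect_error(train_unet(man, unet_config("desk")), "vessel mask")

  phs <- tiny_phantoms(4, size = 32)
  cfg <- unet_config("desk", depth = 3, base_channels = 4, epochs = 1,
                     rng_seed = 5)
  m <- train_unet(NULL, cfg, images = lapply(phs, `[[`, "image"),
                  masks = lapply(phs, `[[`, "vessel_mask"))
  expect_true(all(is.finite(m$history$loss)))
})

test_that("a short training learns bright-vessel segmentation", {
  phs <- tiny_phantoms(8, size = 32, seed0 = 300)
  cfg <- unet_config("desk", depth = 3, base_channels = 6, epochs = 25,
                     learning_rate = 1.5e-3, rng_seed = 6)
  m <- train_unet(NULL, cfg, images = lapply(phs, `[[`, "image"),
                  masks = lapply(phs, `[[`, "vessel_mask"))
  held <- tiny_phantoms(2, size = 32, seed0 = 400)
  d <- vapply(held, function(ph) {
    dice((unet_predict(ph$image, m) > 0.5) * 1, ph$vessel_mask * 1)
  }, numeric(1))
  expect_gt(mean(d), 0.5)
})
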