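# Autoregressive prior: causality, normalization, scoring and
# calibration.

test_that("full-grid probabilities sum to one on enumerable instances", {
  set.seed(1)
  cfg <- ar_config("desk", codebook_k = 3, channels = 8)
  m <- ar_model(cfg)
  grids <- expand.grid(a = 1:3, b = 1:3, c = 1:3, d = 1:3)
  tot <- sum(vapply(seq_len(nrow(grids)), function(r) {
    z <- matrix(as.integer(grids[r, ]), 2, 2)
    exp(-sum(nll_map(z, m)))
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("NLL is causal in raster order", {
  set.seed(2)
  cfg <- ar_config("desk", codebook_k = 5, channels = 8)
  m <- ar_model(cfg)
  z <- matrix(sample(1:5, 36, TRUE), 6, 6)
  n1 <- nll_map(z, m)
  for (t in 1:10) {
    i <- sample(2:6, 1); j <- sample(2:6, 1)
    z2 <- z
    z2[i, j] <- (z2[i, j] %% 5) + 1L
    n2 <- nll_map(z2, m)
    pos <- (i - 1) * 6 + j  # raster (row-major) index of the flip
    expect_identical(raster_vec(n1)[seq_len(pos - 1)],
                     raster_vec(n2)[seq_len(pos - 1)])
  }
})

test_that("an all-masked model yields the uniform NLL", {
  cfg <- ar_config("desk", codebook_k = 32, channels = 8)
  m <- ar_model(cfg)
  for (l in nn_collect(m$net)) { l$W[] <- 0; l$b[] <- 0 }
  n <- nll_map(matrix(1L, 4, 4), m)
  expect_equal(max(abs(n - log(32))), 0, tolerance = 1e-12)
})

test_that("scan score sums strictly-above-threshold cells", {
  expect_equal(scan_score(matrix(c(1, 8, 9), 1, 3), 7), 17)
  expect_equal(scan_score(matrix(c(1, 2, 3), 1, 3), 7), 0)
  expect_equal(scan_score(matrix(c(1, 2, 3), 1, 3), 0), 6)
  # cells equal to the threshold are excluded (strict >)
  expect_equal(scan_score(matrix(c(7, 8), 1, 2), 7), 8)
  # monotone: raising any cell never lowers the score
  set.seed(3)
  n <- matrix(rexp(16), 4, 4)
  s0 <- scan_score(n, 1)
  for (t in 1:10) {
    n2 <- n
    i <- sample(16, 1)
    n2[i] <- n2[i] + rexp(1)
    expect_gte(scan_score(n2, 1), s0)
  }
})

test_that("threshold calibration uses linear-interpolation percentiles", {
  expect_equal(calibrate_t_ar(1:100, 95), 95.05)
  expect_equal(calibrate_t_ar(rep(3.2, 10), 50), 3.2)
  expect_equal(calibrate_t_ar(c(4, 1, 9), 100), 9)
  expect_error(calibrate_t_ar(numeric(0)), "empty")
})

test_that("training shrinks the NLL of a degenerate distribution", {
  set.seed(4)
  z0 <- matrix(sample(1:4, 64, TRUE), 8, 8)
  cfg <- ar_config("desk", codebook_k = 4, channels = 16, epochs = 100,
                   learning_rate = 2e-3, rng_seed = 5)
  m <- train_ar(replicate(8, z0, simplify = FALSE), cfg)
  expect_lt(mean(nll_map(z0, m)), 0.05)
  expect_true(all(is.finite(m$history$nll)))
})

test_that("healthy-like grids score lower than shuffled grids", {
  # structured grids share local statistics; shuffling destroys them
  set.seed(6)
  make_grid <- function() {
    base <- matrix(1L, 12, 12)
    base[, sample(4:8, 1):12] <- 2L
    base
  }
  train <- replicate(12, make_grid(), simplify = FALSE)
  cfg <- ar_config("desk", codebook_k = 2, channels = 16, epochs = 40,
                   rng_seed = 7)
  m <- train_ar(train, cfg)
  held <- make_grid()
  shuffled <- matrix(sample(as.vector(held)), 12, 12)
  expect_lt(mean(nll_map(held, m)), mean(nll_map(shuffled, m)))
})

test_that("empty latent dataset is rejected and smoke run works", {
  expect_error(train_ar(list(), ar_config("desk")), "empty")
  cfg <- ar_config("desk", codebook_k = 4, channels = 4, epochs = 1,
                   rng_seed = 8)
  m <- train_ar(list(matrix(1L, 8, 8)), cfg)
  expect_true(is.finite(m$history$nll[1]))
  expect_error(nll_map(matrix(9L, 8, 8), m), "1..K")
})
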