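# Standardisation and Hessian-eigenvalue vessel enhancement.

test_that("standardize resizes, center-crops and rescales", {
  cfg <- preprocess_config()  # 512 -> 480 full-resolution setting
  set.seed(1)
  x <- matrix(runif(1024 * 1024), 1024, 1024)
  s <- standardize(x, cfg)
  expect_equal(dim(s), c(480, 480))
  expect_equal(range(s), c(0, 1))
  # idempotent on already-standardized images
  expect_identical(standardize(s, cfg), s)
  # identity crop: only rescaling happens
  cfg2 <- preprocess_config(resize_to = 64, crop_to = 64)
  y <- matrix(runif(64 * 64), 64, 64)
  expect_equal(standardize(y, cfg2), rescale01(y))
  # constant input maps to 0 (min-max convention)
  expect_true(all(standardize(matrix(0.7, 64, 64), cfg2) == 0))
  expect_error(standardize(array(0, c(4, 4, 2)), cfg), "2-D")
  expect_error(preprocess_config(resize_to = 64, crop_to = 128),
               "crop_to")
})

test_that("center crop margins are equal with top-left tie break", {
  cfg <- preprocess_config(resize_to = 7, crop_to = 4)
  x <- matrix(seq_len(49), 7, 7)
  s <- standardize(x, cfg)
  # offset floor((7-4)/2) = 1: rows/cols 2..5
  expect_equal(s, rescale01(x[2:5, 2:5]))
})

test_that("hessian of analytic surfaces matches closed forms", {
  cfg <- preprocess_config()
  # constant image: zero matrix everywhere
  H0 <- hessian_matrix(matrix(1, 32, 32), 1)
  expect_true(all(abs(unlist(H0)) < 1e-12))
  # f(x, y) = x^2 along rows: hxx = 2 h^2 (grid step h), others 0
  h <- 1 / 8
  g <- outer((1:64) * h, rep(1, 64))^2
  H <- hessian_matrix(g, 1)
  expect_equal(H$hxx[32, 32], 2 * h^2, tolerance = 1e-8)
  expect_equal(H$hyy[32, 32], 0, tolerance = 1e-10)
  expect_equal(H$hxy[32, 32], 0, tolerance = 1e-10)
})

test_that("hessian equals central differences of the smoothed image", {
  set.seed(2)
  img <- matrix(rnorm(40 * 40), 40, 40)
  scale <- 1.5
  H <- hessian_matrix(img, scale)
  f <- gaussian_smooth(img, scale)
  # naive loop-based oracle on the interior
  for (t in 1:20) {
    i <- sample(3:38, 1); j <- sample(3:38, 1)
    expect_equal(H$hxx[i, j], f[i + 1, j] - 2 * f[i, j] + f[i - 1, j],
                 tolerance = 1e-6)
    expect_equal(H$hyy[i, j], f[i, j + 1] - 2 * f[i, j] + f[i, j - 1],
                 tolerance = 1e-6)
    fxy <- (f[i + 1, j + 1] - f[i + 1, j - 1] -
              f[i - 1, j + 1] + f[i - 1, j - 1]) / 4
    expect_equal(H$hxy[i, j], fxy, tolerance = 1e-6)
  }
})

test_that("eigenvalues satisfy algebraic identities and ordering", {
  # closed-form cases
  ev <- hessian_eigenvalues(list(hxx = matrix(2), hxy = matrix(0),
                                 hyy = matrix(0)))
  expect_equal(ev$lambda1[1, 1], 0)
  expect_equal(ev$lambda2[1, 1], 2)
  ev2 <- hessian_eigenvalues(list(hxx = matrix(0), hxy = matrix(1),
                                  hyy = matrix(0)))
  # |.|-tie broken by signed ascending: lambda1 = -1, lambda2 = +1
  expect_equal(ev2$lambda1[1, 1], -1)
  expect_equal(ev2$lambda2[1, 1], 1)
  # random fields: trace and determinant preserved, |l1| <= |l2|
  set.seed(3)
  H <- list(hxx = matrix(rnorm(100), 10), hxy = matrix(rnorm(100), 10),
            hyy = matrix(rnorm(100), 10))
  ev3 <- hessian_eigenvalues(H)
  expect_lt(max(abs(ev3$lambda1 + ev3$lambda2 - (H$hxx + H$hyy))), 1e-9)
  expect_lt(max(abs(ev3$lambda1 * ev3$lambda2 -
                      (H$hxx * H$hyy - H$hxy^2))), 1e-9)
  expect_true(all(abs(ev3$lambda1) <= abs(ev3$lambda2) + 1e-12))
})

test_that("vesselness responds on ridges and is offset invariant", {
  cfg <- preprocess_config(vesselness_scales = c(1, 2))
  # constant image: all-zero response
  expect_true(all(vesselness_enhance(matrix(0.4, 48, 48), cfg) == 0))
  # bright line on dark background
  ph <- matrix(0.05, 64, 64)
  ph[, 30:32] <- 1
  v <- vesselness_enhance(ph, cfg)
  expect_gt(mean(v[, 31]), mean(v[, c(5:20, 45:60)]))
  expect_true(all(v >= 0 & v <= 1))
  # adding a constant leaves the response unchanged
  v2 <- vesselness_enhance(ph + 0.2, cfg)
  expect_equal(v, v2, tolerance = 1e-10)
})

test_that("vesselness is equivariant to 90-degree rotation", {
  cfg <- preprocess_config(vesselness_scales = c(1, 2))
  set.seed(4)
  z <- gaussian_smooth(matrix(runif(48 * 48), 48, 48), 1)
  rot <- function(m) t(apply(m, 2, rev))
  expect_equal(vesselness_enhance(rot(z), cfg),
               rot(vesselness_enhance(z, cfg)), tolerance = 1e-10)
})
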