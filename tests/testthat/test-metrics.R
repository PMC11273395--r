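# Evaluation metrics against independent oracles.

test_that("dice handles identity, disjoint and counted overlaps", {
  a <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2)
  b <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 2)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  expect_equal(dice(a, b), 0.5)  # |A|=|B|=4, overlap 2
  z <- matrix(0, 2, 4)
  expect_equal(dice(z, z), 1)    # both-empty convention
  expect_error(dice(a, matrix(0, 3, 3)), "shapes")
})

test_that("iou/sensitivity/specificity match a confusion-matrix tally", {
  set.seed(1)
  for (t in 1:10) {
    p <- matrix(rbinom(60, 1, 0.4), 6, 10)
    g <- matrix(rbinom(60, 1, 0.4), 6, 10)
    m <- iou_sens_spec(p, g)
    tp <- sum(p == 1 & g == 1); fp <- sum(p == 1 & g == 0)
    fn <- sum(p == 0 & g == 1); tn <- sum(p == 0 & g == 0)
    expect_equal(m$iou, tp / (tp + fp + fn))
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    # algebraic identity with dice
    d <- dice(p, g)
    expect_equal(m$iou, d / (2 - d), tolerance = 1e-12)
  }
  m1 <- iou_sens_spec(matrix(1, 2, 2), matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(m1$sensitivity, 1)
  expect_equal(m1$specificity, 0)
  ident <- iou_sens_spec(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_equal(unlist(ident), c(iou = 1, sensitivity = 1,
                                specificity = 1))
})

test_that("auroc equals the pairwise Mann-Whitney probability", {
  set.seed(2)
  for (t in 1:10) {
    n0 <- sample(4:12, 1); n1 <- sample(4:12, 1)
    sc <- c(round(rnorm(n0), 1), round(rnorm(n1, 0.5), 1))  # force ties
    lb <- c(rep(0, n0), rep(1, n1))
    brute <- mean(outer(sc[lb == 1], sc[lb == 0],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(sc, lb), brute, tolerance = 1e-9)
    # complement identity (ties counted 1/2 keep it exact)
    expect_equal(auroc(sc, lb) + auroc(-sc, lb), 1, tolerance = 1e-9)
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auroc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  sc <- rnorm(40)
  lb <- rbinom(40, 1, 0.4)
  if (length(unique(lb)) < 2) lb[1] <- 1 - lb[1]
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<"))))
  expect_equal(auroc(sc, lb), ref, tolerance = 1e-12)
})

test_that("average precision follows the step-wise PR definition", {
  expect_equal(average_precision(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # positive ranked second of two: P = 1/2 at R = 1
  expect_equal(average_precision(c(2, 1), c(0, 1)), 0.5)
  # hand-enumerated: scores 4>3>2>1, labels 1,0,1,0
  # threshold steps: R=1/2 P=1; R=1 P=2/3 -> AP = 1/2*1 + 1/2*2/3
  expect_equal(average_precision(c(1, 2, 3, 4), c(0, 1, 0, 1)),
               0.5 * 1 + 0.5 * 2 / 3)
  # rank statistic: invariant under strictly monotone transforms
  set.seed(4)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  if (length(unique(lb)) < 2) lb[1] <- 1 - lb[1]
  expect_equal(average_precision(sc, lb),
               average_precision(exp(sc), lb), tolerance = 1e-12)
  # permutation invariance
  ord <- sample(30)
  expect_equal(average_precision(sc[ord], lb[ord]),
               average_precision(sc, lb), tolerance = 1e-12)
})

test_that("Youden operating point matches a brute-force scan", {
  expect_equal(f1_at_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))$f1, 1)
  th <- f1_at_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))$threshold
  expect_true(th > 2 && th < 3)
  set.seed(5)
  for (t in 1:10) {
    sc <- round(rnorm(20), 1)
    lb <- rbinom(20, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1] <- 1 - lb[1]
    got <- f1_at_youden(sc, lb)
    # brute force over a fine threshold grid
    grid <- sort(unique(c(sc - 1e-6, sc + 1e-6, min(sc) - 1)))
    best_j <- -Inf
    for (th in grid) {
      pred <- sc > th
      tp <- sum(pred & lb == 1); fp <- sum(pred & lb == 0)
      fn <- sum(!pred & lb == 1); tn <- sum(!pred & lb == 0)
      j <- tp / (tp + fn) + tn / (tn + fp) - 1
      best_j <- max(best_j, j)
    }
    pred <- sc > got$threshold
    tp <- sum(pred & lb == 1); fp <- sum(pred & lb == 0)
    fn <- sum(!pred & lb == 1); tn <- sum(!pred & lb == 0)
    j_got <- tp / (tp + fn) + tn / (tn + fp) - 1
    expect_equal(j_got, best_j, tolerance = 1e-9)
  }
})

test_that("scan and pixel reports aggregate correctly", {
  sc <- c(0.1, 0.2, 0.9, 1.4)
  lb <- c(0, 0, 1, 1)
  rep <- scan_eval_report(sc, lb)
  expect_equal(rep$auroc, 1)
  expect_equal(rep$average_precision, 1)
  expect_equal(rep$f1_at_youden, 1)
  p <- list(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
  g <- list(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 1, 0, 0), 2))
  pr <- pixel_eval_report(p, g)
  expect_equal(nrow(pr$per_image), 2)
  expect_equal(pr$per_image$dice[1], 1)
  expect_equal(pr$summary$mean[pr$summary$metric == "dice"],
               mean(pr$per_image$dice))
  # iou = dice/(2 - dice) per image
  expect_equal(pr$per_image$iou,
               pr$per_image$dice / (2 - pr$per_image$dice),
               tolerance = 1e-12)
})
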