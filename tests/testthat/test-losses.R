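test_that("gradient correlation matches the brute-force definition", {
  set.seed(11)
  for (i in 1:5) {
    y <- matrix(runif(256), 16); yh <- matrix(runif(256), 16)
    expect_equal(gradient_correlation(y, yh), oracle_gc(y, yh),
                 tolerance = 1e-10)
    expect_equal(gradient_correlation(y, yh), gradient_correlation(yh, y),
                 tolerance = 1e-12)
  }
  y <- matrix(runif(256), 16)
  expect_equal(gradient_correlation(y, y), 1, tolerance = 1e-12)
  expect_equal(gradient_correlation(y, 2.5 * y + 0.3), 1, tolerance = 1e-12)
  expect_warning(gc0 <- gradient_correlation(y, matrix(0.5, 16, 16)),
                 "zero-variance")
  expect_equal(gc0, 0)
})

test_that("separation loss vanishes at the target and penalizes shuffles", {
  set.seed(12)
  y <- matrix(runif(256), 16)
  expect_equal(separation_loss(y, y), 0, tolerance = 1e-12)
  sh <- matrix(sample(y), 16)
  expect_gt(separation_loss(y, sh), separation_loss(y, y))
  # all-zero prediction against all-one target under the zero-variance guard
  suppressWarnings(
    l <- separation_loss(matrix(1, 8, 8), matrix(0, 8, 8)))
  expect_equal(l, 0.5 * (1 + (1 - 0)))
})

test_that("binary cross-entropy matches its closed forms", {
  half <- matrix(0.5, 4, 4)
  expect_equal(bce_loss(half, half), log(2), tolerance = 1e-12)
  y <- matrix(rep(c(0, 1), 8), 4)
  expect_lt(bce_loss(y, y), 1.1e-7)
  set.seed(13)
  for (i in 1:5) {
    yy <- matrix(runif(64), 8); ph <- matrix(runif(64), 8)
    expect_equal(bce_loss(yy, ph), oracle_bce(yy, ph), tolerance = 1e-10)
  }
})

test_that("dice plus cross-entropy matches the brute-force evaluation", {
  set.seed(14)
  n <- 16^3
  y <- (runif(n) > 0.8) * 1
  Y <- cbind(1 - y, y)
  # perfect one-hot prediction (clipped inside the loss)
  expect_lt(dice_ce_loss(Y, Y), 1e-6)
  # uniform prediction over two classes
  U <- matrix(0.5, n, 2)
  expect_equal(dice_ce_loss(Y, U), oracle_dice_ce(Y, U), tolerance = 1e-10)
  # random softmax prediction
  z <- matrix(rnorm(2 * n), n, 2)
  P <- exp(z) / rowSums(exp(z))
  expect_equal(dice_ce_loss(Y, P), oracle_dice_ce(Y, P), tolerance = 1e-10)
  # disjoint prediction: the Dice part equals the class count
  D <- cbind(y, 1 - y)
  ce <- -sum(Y * log(pmin(pmax(D, 1e-7), 1 - 1e-7))) / n
  expect_equal(dice_ce_loss(Y, D) - ce, 2, tolerance = 1e-9)
  # non-normalized predictions violate the contract
  expect_error(dice_ce_loss(Y, Y * 0.7), "contract violation")
})

test_that("all losses are non-negative and minimal at the target", {
  set.seed(15)
  y <- matrix(runif(144), 12)
  expect_gte(separation_loss(y, matrix(runif(144), 12)), 0)
  expect_gte(bce_loss(y, matrix(runif(144), 12)), bce_loss(y, y) - 1e-12)
  t <- (runif(64) > 0.5) * 1; Y <- cbind(1 - t, t)
  z <- matrix(rnorm(128), 64, 2); P <- exp(z) / rowSums(exp(z))
  expect_gte(dice_ce_loss(Y, P), 0)
  expect_lt(dice_ce_loss(Y, Y), dice_ce_loss(Y, P))
})
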