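test_that("separation model emits two bounded images from one encoder", {
  cfg <- network_config("separation", input_size = 64, base_channels = 4,
                        seed = 2)
  m <- build_separation_model(cfg)
  x <- matrix(runif(64 * 64), 64)
  out <- predict_model(m, x)
  expect_equal(dim(out$R), c(64, 64))
  expect_equal(dim(out$L), c(64, 64))
  expect_true(all(out$R >= 0 & out$R <= 1))
  # architectural symmetry of the two decoder branches
  counts <- model_param_counts(m)
  expect_equal(unname(counts["dR"]), unname(counts["dL"]))
})

test_that("one optimization step decreases the separation loss", {
  cfg <- network_config("separation", input_size = 32, base_channels = 4,
                        seed = 3)
  m <- build_separation_model(cfg)
  set.seed(4)
  x <- matrix(runif(32 * 32), 32)
  smp <- list(list(x = x, y = list(R = x * 0.8, L = x * 0.2)))
  l0 <- osteoplan:::model_sample_pass(m, smp[[1]], FALSE)$loss
  mt <- train_network(m, smp, epochs = 3, learning_rate = 1e-3,
                      batch_size = 1, seed = 1)
  expect_lt(tail(mt$history$train, 1), l0)
})

test_that("landmark model shapes, range, and one-sample overfit", {
  cfg <- network_config("landmarks", input_size = 32, base_channels = 4,
                        seed = 5)
  m <- build_landmark_model(cfg, 3)
  x <- matrix(runif(32 * 32), 32)
  hm0 <- predict_model(m, x)
  expect_equal(dim(hm0), c(32, 32, 3))
  expect_true(all(hm0 >= 0 & hm0 <= 1))
  y <- make_heatmaps(list(a = c(8, 9), b = c(20, 15), c = c(11, 25)),
                     sigma = 3, shape = c(32, 32))
  smp <- list(list(x = x, y = y))
  l0 <- osteoplan:::model_sample_pass(m, smp[[1]], FALSE)$loss
  mt <- train_network(m, smp, epochs = 60, learning_rate = 3e-3, seed = 1)
  expect_lt(tail(mt$history$train, 1), 0.5 * l0)
})

test_that("reconstruction model follows the fusion-cube rule and softmax contract", {
  cfg <- network_config("reconstruction", input_size = 32, base_channels = 4,
                        seed = 6)
  m <- build_reconstruction_model(cfg)
  x <- list(frontal = matrix(runif(1024), 32),
            sagittal = matrix(runif(1024), 32))
  yh <- predict_model(m, x)
  expect_equal(attr(yh, "n"), 8)   # input edge / 4
  expect_equal(nrow(yh), 8^3)
  expect_equal(rowSums(yh), rep(1, 8^3), tolerance = 1e-6)
  cfg128 <- network_config("reconstruction", input_size = 128)
  expect_equal(cfg128$input_size / 4, 32)
  expect_error(network_config("reconstruction", input_size = 100),
               "config error")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- network_config("landmarks", input_size = 32, base_channels = 2,
                        seed = 7)
  y <- make_heatmaps(list(a = c(10, 10)), sigma = 3, shape = c(32, 32))
  set.seed(8); x <- matrix(runif(1024), 32)
  smp <- list(list(x = x, y = y[, , 1, drop = FALSE]))
  m1 <- train_network(build_landmark_model(cfg, 3), list(
    list(x = x, y = y[, , c(1, 1, 1)])), epochs = 3, seed = 9)
  m2 <- train_network(build_landmark_model(cfg, 3), list(
    list(x = x, y = y[, , c(1, 1, 1)])), epochs = 3, seed = 9)
  expect_equal(tail(m1$history$train, 1), tail(m2$history$train, 1),
               tolerance = 1e-6)
  expect_error(train_network(build_landmark_model(cfg, 3), list()),
               "data error")
})

test_that("landmark decoding recovers peaks with deterministic tie-breaks", {
  # synthesized continuous Gaussian: recovered to half a pixel
  set.seed(10)
  us <- matrix(rep(0:31, each = 32), 32, 32)
  vs <- matrix(rep(0:31, times = 32), 32, 32)
  for (i in 1:8) {
    lm <- c(u = runif(1, 5, 26), v = runif(1, 5, 26))
    ch <- exp(-((us - lm["u"])^2 + (vs - lm["v"])^2) / (2 * 16))
    got <- extract_landmark(ch)
    expect_lt(sqrt(sum((got - lm)^2)), 0.5 + 1e-9)
  }
  # single nonzero pixel
  ch <- matrix(0, 16, 16); ch[5, 9] <- 0.3
  expect_equal(unname(extract_landmark(ch)), c(8, 4))
  # two equal peaks: lowest (v, then u) wins
  ch2 <- matrix(0, 16, 16); ch2[12, 3] <- 1; ch2[4, 14] <- 1
  got <- extract_landmark(ch2)
  expect_equal(unname(round(got)), c(13, 3))
  # all-zero channel: sentinel
  expect_true(all(is.na(extract_landmark(matrix(0, 8, 8)))))
})

test_that("study inference keeps the two legs independent", {
  st <- fix_study()
  cfg <- network_config("reconstruction",
                        input_size = 128, base_channels = 2, seed = 11)
  models <- list(reconstruction = build_reconstruction_model(cfg))
  pr <- predict_study(models, st, separation_mode = "oracle",
                      use_true_landmarks = TRUE)
  expect_true(all(pr$recon$right$pred %in% c(TRUE, FALSE)))
  pr_right_only <- predict_study(models, st, separation_mode = "oracle",
                                 use_true_landmarks = TRUE, sides = "right")
  expect_equal(pr$recon$right$prob, pr_right_only$recon$right$prob)
  expect_error(predict_study(list(), st, separation_mode = "network"),
               "pipeline error")
})
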