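test_that("adversarial objective matches its closed forms and an elementwise oracle", {
  expect_equal(cganObjective(0.5, 0.5), 2 * log(0.5))
  expect_equal(cganObjective(rep(0.5, 64), rep(0.5, 64)), 2 * log(0.5))
  # perfect-discriminator limit
  expect_gt(cganObjective(1 - 1e-9, 1e-9), -1e-6)
  expect_error(cganObjective(1.2, 0.5), "\\[0, 1\\]")

  set.seed(10)
  for (i in 1:20) {
    r <- runif(37); f <- runif(37)
    manual <- sum(log(r)) / 37 + sum(log(1 - f)) / 37
    expect_equal(cganObjective(r, f), manual, tolerance = 1e-12)
  }
})

test_that("the L1 term is the per-pixel mean absolute deviation", {
  a <- matrix(runif(64), 8, 8)
  expect_identical(l1Term(a, a), 0)
  expect_equal(l1Term(a, a + 0.3), 0.3)
  set.seed(11)
  b <- matrix(runif(64), 8, 8)
  manual <- sum(abs(a - b)) / 64
  expect_equal(l1Term(a, b), manual, tolerance = 1e-12)
  expect_error(l1Term(a, matrix(0, 4, 4)), "shapes differ")
})

test_that("combined generator loss applies the lambda weighting", {
  a <- matrix(0.2, 8, 8); b <- matrix(0.7, 8, 8)  # L1 = 0.5
  s <- rep(0.4, 16)
  g <- -mean(log(s))
  expect_equal(combinedGeneratorLoss(s, a, b, lambda = 100), g + 50)
  expect_equal(combinedGeneratorLoss(s, a, b, lambda = 0), g)
  # minimax form
  expect_equal(combinedGeneratorLoss(s, a, b, lambda = 0, nonSaturating = FALSE),
               mean(log(1 - s)))
  # strictly increasing in the reconstruction error when lambda > 0
  worse <- matrix(0.9, 8, 8)
  expect_gt(combinedGeneratorLoss(s, a, worse, lambda = 100),
            combinedGeneratorLoss(s, a, b, lambda = 100))
})

test_that("summed cross-entropy matches closed forms and the triple-loop oracle", {
  # perfect one-hot prediction: zero loss
  Q <- array(0, c(4, 4, 2)); Q[, , 1] <- 1
  expect_equal(fcnLoss(Q, Q), 0)
  # uniform over 2 classes on w x h pixels: w*h*ln 2
  P <- array(0.5, c(4, 4, 2))
  expect_equal(fcnLoss(P, Q), 16 * log(2))

  set.seed(12)
  for (i in 1:10) {
    z <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
    P <- exp(z); P <- P / array(rep(apply(P, c(1, 2), sum), 3), dim(P))
    lab <- array(sample(0:2, 30, TRUE), c(6, 5))
    Q <- array(0, c(6, 5, 3))
    for (k in 0:2) Q[, , k + 1][lab == k] <- 1
    expect_equal(fcnLoss(P, Q), oracleFcnLoss(P, Q), tolerance = 1e-10)
  }
  # dividing by w*h recovers the mean cross-entropy
  expect_equal(fcnLoss(P, Q) / (6 * 5),
               -mean(log(P[Q == 1])), tolerance = 1e-12)
})

test_that("segmenter output is a per-pixel distribution and prediction breaks ties low", {
  m <- segNetwork(classes = 3, depth = 4, baseWidth = 2, seed = 20)
  img <- matrix(runif(16 * 16), 16, 16)
  P <- segForward(m, img)
  expect_equal(dim(P), c(16, 16, 3))
  expect_equal(apply(P, c(1, 2), sum), matrix(1, 16, 16), tolerance = 1e-6)
  expect_identical(P, segForward(m, img))  # deterministic in eval mode
  expect_error(segForward(m, array(0, c(16, 16, 2, 1))), "single-channel")

  # argmax of an exactly uniform distribution picks class 0 everywhere
  uni <- array(1 / 3, c(8, 8, 3))
  expect_true(all(irisynth:::argmaxClasses(uni) == 0L))
})

test_that("a short segmentation run decreases the loss and is seed-stable", {
  ds <- renderDataset(32, toyRanges(32), renderConfig(), c(32, 32), seed = 41)
  cfg <- segConfig(classes = 2, lr = 1e-4, batchSize = 8, epochs = 3,
                   baseWidth = 4, seed = 42)
  fit <- trainSegmentation(ds$images, ds$irisMasks, cfg)
  expect_identical(nrow(fit$history), 3L)
  expect_lt(fit$history$loss[3], fit$history$loss[1])
  fit2 <- trainSegmentation(ds$images, ds$irisMasks, cfg)
  expect_identical(fit$history, fit2$history)
  pred <- predictMask(fit$model, ds$images[, , 1])
  expect_true(all(pred %in% c(0L, 1L)))
})
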