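test_that("confusion matrices equal per-pixel enumeration", {
  pred <- c(0L, 0L, 1L, 1L)
  true <- c(0L, 0L, 0L, 1L)
  cm <- pixelConfusion(pred, true, 2)
  expect_identical(cm, matrix(c(2L, 1L, 0L, 1L), 2, 2, byrow = TRUE))
  expect_error(pixelConfusion(c(0, 2), c(0, 0), 2), "\\[0, k\\)")

  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    p <- sample(0:(k - 1), 60, TRUE)
    t <- sample(0:(k - 1), 60, TRUE)
    expect_identical(pixelConfusion(p, t, k), oracleConfusion(p, t, k))
  }
})

test_that("PA, mPA, mIoU and FWIoU agree with direct formula enumeration", {
  # perfect prediction: all four metrics are exactly 1
  cm <- diag(c(10, 20, 5))
  expect_equal(segmentationMetrics(cm),
               c(PA = 1, mPA = 1, mIoU = 1, FWIoU = 1))
  # fully wrong binary prediction: IoU collapses to 0
  cmw <- matrix(c(0, 7, 3, 0), 2, 2, byrow = TRUE)
  expect_equal(meanIoU(cmw), 0)
  # spot value
  expect_equal(pixelAccuracy(matrix(c(3, 1, 0, 0), 2, 2, byrow = TRUE)), 0.75)
  # single-class ground truth: FWIoU equals that class's IoU
  cm1 <- matrix(c(8, 2, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(fwIoU(cm1), 8 / 10)

  set.seed(14)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    p <- sample(0:(k - 1), 50, TRUE)
    t <- sample(0:(k - 1), 50, TRUE)
    cm <- pixelConfusion(p, t, k)
    o <- oracleMetrics(cm)
    expect_equal(pixelAccuracy(cm), unname(o["PA"]), tolerance = 1e-12)
    expect_equal(meanPixelAccuracy(cm), unname(o["mPA"]), tolerance = 1e-12)
    expect_equal(meanIoU(cm), unname(o["mIoU"]), tolerance = 1e-12)
    expect_equal(fwIoU(cm), unname(o["FWIoU"]), tolerance = 1e-12)
  }
})

test_that("metrics are 1 exactly when the confusion matrix is diagonal", {
  set.seed(15)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    t <- sample(0:(k - 1), 40, TRUE)
    cm <- pixelConfusion(t, t, k)
    expect_equal(unname(segmentationMetrics(cm)), rep(1, 4))
    wrong <- t; wrong[1] <- (wrong[1] + 1L) %% k
    expect_true(all(segmentationMetrics(pixelConfusion(wrong, t, k)) < 1))
  }
})

test_that("feature statistics estimate the embedding moments", {
  imgs <- array(0.5, c(8, 8, 4))
  s <- featureStatistics(imgs)
  expect_equal(max(abs(s@sigma)), 0)            # identical images
  expect_error(featureStatistics(imgs[, , 1, drop = FALSE]), "at least 2")

  # two scalar embeddings {0, 2} -> mean 1
  s2 <- featureStatistics(list(matrix(0, 2, 2), matrix(2, 2, 2)),
                          embedder = function(im) mean(im))
  expect_equal(unname(s2@mu), 1)

  # moments of a known Gaussian embedding recovered within 3 SEs
  set.seed(16)
  imgs <- lapply(1:4000, function(i) matrix(rnorm(1, 2, 0.5), 1, 1))
  s3 <- featureStatistics(imgs, embedder = function(im) as.numeric(im))
  expect_lt(abs(s3@mu - 2), 3 * 0.5 / sqrt(4000))
  expect_lt(abs(s3@sigma[1, 1] - 0.25), 3 * sqrt(2 / 3999) * 0.25)
})

test_that("Frechet distance: identity, closed form, and eigendecomposition oracle", {
  set.seed(17)
  mkStats <- function(mu, S, n = 10L) new("FeatureStatistics", mu = mu,
                                          sigma = S, n = n)
  A <- matrix(rnorm(9), 3, 3); S <- A %*% t(A)
  s <- mkStats(rnorm(3), S)
  expect_equal(fidScore(s, s), 0, tolerance = 1e-8)

  # 1-D Gaussians N(0,1) vs N(m,1): distance m^2
  for (m in c(0.5, 1, 2))
    expect_equal(fidScore(mkStats(0, matrix(1, 1, 1)),
                          mkStats(m, matrix(1, 1, 1))), m^2, tolerance = 1e-10)

  for (i in 1:20) {
    A1 <- matrix(rnorm(16), 4, 4); S1 <- A1 %*% t(A1) + diag(4) * 0.1
    A2 <- matrix(rnorm(16), 4, 4); S2 <- A2 %*% t(A2) + diag(4) * 0.1
    m1 <- rnorm(4); m2 <- rnorm(4)
    expect_equal(fidScore(mkStats(m1, S1), mkStats(m2, S2)),
                 oracleFid(m1, S1, m2, S2), tolerance = 1e-6)
    # symmetry in the arguments
    expect_equal(fidScore(mkStats(m1, S1), mkStats(m2, S2)),
                 fidScore(mkStats(m2, S2), mkStats(m1, S1)), tolerance = 1e-8)
  }
  expect_error(fidScore(mkStats(rnorm(3), diag(3)), mkStats(rnorm(2), diag(2))),
               "dimensions differ")
})

test_that("directory-based evaluation aggregates one confusion matrix", {
  dp <- withr::local_tempdir(); dt <- withr::local_tempdir()
  set.seed(18)
  for (i in 1:3) {
    t <- matrix(rbinom(64, 1, 0.4), 8, 8)
    p <- t; flip <- sample(64, 5); p[flip] <- 1L - p[flip]
    writeMaskPNG(t, file.path(dt, sprintf("m%02d.png", i)))
    writeMaskPNG(p, file.path(dp, sprintf("m%02d.png", i)))
  }
  ev <- evaluateMasks(dp, dt)
  expect_equal(sum(ev$confusion), 3 * 64)
  expect_equal(sum(ev$confusion) - sum(diag(ev$confusion)), 15)
  expect_true(all(ev$metrics >= 0 & ev$metrics <= 1))
})
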