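# Architecture arithmetic and differentiation correctness of the
# hand-built convolutional stack.

test_that("generator halves spatial size per level down to a 1x1 bottleneck", {
  g <- generatorNetwork(depth = 6, baseWidth = 4, seed = 1)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2, 1))
  fw <- irisynth:::unetForward(g, x)
  sizes <- vapply(fw$cache$enc, function(cc) dim(cc$x)[1], numeric(1))
  expect_equal(sizes, 64 / 2^(0:5))          # inputs to each encoder layer
  expect_equal(dim(fw$cache$dec[[1]]$x)[1:2], c(1, 1))  # bottleneck
  expect_equal(dim(fw$y), c(64, 64, 1, 1))
})

test_that("discriminator feature maps follow 256 / 2^l; 4th layer is 16x16", {
  d <- discriminatorNetwork(baseWidth = 2, seed = 1)
  sz <- discriminatorFeatureSizes(d, c(256, 256))
  expect_equal(unname(sz[, "height"]), 256 / 2^(1:5))
  expect_equal(unname(sz["conv4", ]), c(16, 16))
  expect_equal(unname(sz["conv5", ]), c(8, 8))
})

test_that("forward passes respect ranges, shapes and determinism", {
  g <- generatorNetwork(depth = 5, baseWidth = 4, seed = 2)
  x <- array(0, c(32, 32, 2, 1))
  y1 <- generatorForward(g, x)
  expect_true(all(y1 > 0 & y1 < 1))          # sigmoid range, all-zero input
  expect_identical(y1, generatorForward(g, x))
  expect_error(generatorForward(g, array(0, c(24, 24, 2, 1))), "divisible")
  expect_error(generatorForward(g, array(0, c(32, 32, 3, 1))), "channels")

  d <- discriminatorNetwork(baseWidth = 2, seed = 3)
  img <- matrix(runif(32 * 32), 32, 32)
  s <- discriminatorForward(d, x[, , , 1][, , 1:2], img)
  expect_true(all(s >= 0 & s <= 1))
  expect_error(discriminatorForward(d, x, matrix(0, 16, 16)), "resolution")
})

test_that("analytic gradients of the full networks match finite differences", {
  numgrad <- function(f, x, eps = 1e-5) {
    g <- x * 0
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      g[i] <- (f(xp) - f(xm)) / (2 * eps)
    }
    g
  }
  relerr <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))

  g <- generatorNetwork(inChannels = 2, outChannels = 1, depth = 3,
                        baseWidth = 2, dropout = 0, seed = 4)
  x <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  tgt <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  fw <- irisynth:::unetForward(g, x)
  bg <- irisynth:::unetBackward(g, fw$cache, gy = tgt)
  lossW <- function(v) {
    g2 <- g; g2$enc[[1]]$W <- array(v, dim(g$enc[[1]]$W))
    sum(irisynth:::unetForward(g2, x)$y * tgt)
  }
  expect_lt(relerr(bg$enc[[1]]$W, numgrad(lossW, as.vector(g$enc[[1]]$W))), 1e-5)
  lossD <- function(v) {
    g2 <- g; g2$dec[[2]]$W <- array(v, dim(g$dec[[2]]$W))
    sum(irisynth:::unetForward(g2, x)$y * tgt)
  }
  expect_lt(relerr(bg$dec[[2]]$W, numgrad(lossD, as.vector(g$dec[[2]]$W))), 1e-5)

  d <- discriminatorNetwork(inChannels = 3, baseWidth = 2, nLayers = 3, seed = 5)
  xd <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  fwd <- irisynth:::chainForward(d, xd)
  tg <- array(rnorm(length(fwd$y)), dim(fwd$y))
  bk <- irisynth:::chainBackward(d, fwd$cache, gy = tg)
  gnum <- numgrad(function(v) sum(irisynth:::chainForward(d, array(v, dim(xd)))$y * tg),
                  as.vector(xd))
  expect_lt(relerr(bk$gx, gnum), 1e-5)       # input gradient drives G updates
})

test_that("a short adversarial run reduces the reconstruction term and is seed-stable", {
  ranges <- toyRanges(32)
  ds <- renderDataset(48, ranges, renderConfig(), c(32, 32), seed = 31)
  x <- irisynth:::stackConditions(ds$irisMasks, ds$periocularMasks)
  cfg <- ganTrainingConfig(batchSize = 8, iterations = 30, baseWidth = 4,
                           discBaseWidth = 4, seed = 32)
  run1 <- trainGenerationModel(x, ds$images, cfg)
  expect_identical(nrow(run1$history), 30L)
  expect_lt(mean(tail(run1$history$gL1, 5)), mean(head(run1$history$gL1, 5)))
  run2 <- trainGenerationModel(x, ds$images, cfg)
  expect_identical(run1$history, run2$history)
})

test_that("synthesized datasets keep their conditioning masks as labels", {
  g <- generatorNetwork(depth = 5, baseWidth = 2, seed = 6)
  synth <- synthesizeDataset(g, 5, toyRanges(32), c(32, 32), seed = 7)
  expect_identical(dim(synth$images), c(32L, 32L, 5L))
  expect_true(all(synth$images > 0 & synth$images < 1))
  for (i in c(1, 5)) {
    cp <- makeConditionPair(synth$params[[i]], c(32, 32),
                            clipToPeriocular = TRUE)
    expect_identical(synth$irisMasks[, , i], unname(irisMask(cp)) + 0L)
    expect_identical(synth$periocularMasks[, , i], unname(periocularMask(cp)) + 0L)
  }
})
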