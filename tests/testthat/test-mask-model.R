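test_that("sampled parameters respect their intervals and the containment invariant", {
  ranges <- defaultParameterRanges()
  draws <- lapply(1:1000, function(s) sampleParameters(ranges, seed = s))
  m <- t(vapply(draws, paramsToVector, numeric(11)))
  expect_true(all(m[, "pupilR"] >= 20 & m[, "pupilR"] <= 60))
  expect_true(all(m[, "irisR"] >= 70 & m[, "irisR"] <= 120))
  expect_true(all(m[, "xRatio"] >= 1.3 & m[, "xRatio"] <= 2.5))
  expect_true(all(m[, "yRatio"] >= 0.4 & m[, "yRatio"] <= 1.1))
  expect_true(all(abs(m[, "degree"]) <= 15))
  expect_true(all(abs(m[, "xOffset"]) <= m[, "xRatio"] * m[, "irisR"] / 2))
  expect_true(all(abs(m[, "yOffset"]) <= m[, "yRatio"] * m[, "irisR"] / 2))
  expect_true(all(m[, "irisX"] >= 0.2 * 640 & m[, "irisX"] <= 0.8 * 640))
  expect_true(all(m[, "irisY"] >= 0.2 * 480 & m[, "irisY"] <= 0.8 * 480))
  d <- sqrt((m[, "pupilX"] - m[, "irisX"])^2 + (m[, "pupilY"] - m[, "irisY"])^2)
  expect_true(all(d + m[, "pupilR"] <= m[, "irisR"] + 1e-9))
})

test_that("sampling is deterministic in the seed and errors on impossible ranges", {
  r <- defaultParameterRanges()
  expect_identical(paramsToVector(sampleParameters(r, seed = 42)),
                   paramsToVector(sampleParameters(r, seed = 42)))
  expect_false(identical(paramsToVector(sampleParameters(r, seed = 1)),
                         paramsToVector(sampleParameters(r, seed = 2))))
  bad <- defaultParameterRanges(pupilR = c(130, 150))
  expect_error(sampleParameters(bad, seed = 1), "no valid configuration")
})

test_that("invalid parameter combinations are rejected", {
  expect_error(maskParameters(320, 240, 110, 320, 240, 100),
               "smaller than irisR")
  expect_error(maskParameters(400, 240, 40, 320, 240, 100),
               "inside the iris circle")
  expect_error(maskParameters(320, 240, 40, 320, 240, 100, xRatio = -1),
               "positive")
})

test_that("annulus rasterization matches the per-pixel brute-force oracle", {
  p <- maskParameters(320, 240, 40, 320, 240, 100)
  m <- rasterizeIrisMask(p, c(480, 640))
  expect_true(all(m %in% c(0L, 1L)))
  expect_identical(sum(m), oracleAnnulusCount(p, 480, 640))
  analytic <- pi * (100^2 - 40^2)
  expect_lt(abs(sum(m) - analytic) / analytic, 0.01)
  # off-centre pupil still inside iris
  p2 <- maskParameters(350, 250, 30, 320, 240, 90)
  m2 <- rasterizeIrisMask(p2, c(480, 640))
  expect_identical(sum(m2), oracleAnnulusCount(p2, 480, 640))
})

test_that("degenerate and clipped annuli behave", {
  # pupil radius just below iris radius: near-empty ring
  p <- maskParameters(320, 240, 100 - 1e-6, 320, 240, 100)
  expect_lt(sum(rasterizeIrisMask(p, c(480, 640))), 700)
  # circle partially outside the frame is clipped, never out of bounds
  p2 <- maskParameters(10, 10, 30, 10, 10, 80)
  m <- rasterizeIrisMask(p2, c(100, 100))
  expect_identical(dim(m), c(100L, 100L))
  expect_lt(sum(m), pi * (80^2 - 30^2))
  expect_error(rasterizeIrisMask(p2, c(0, 100)), "positive")
})

test_that("ellipse rasterization matches its oracle and symmetries", {
  p <- centredParams(256)
  m <- rasterizePeriocularMask(p, c(256, 256))
  expect_identical(sum(m), oracleEllipseCount(p, 256, 256))
  a <- p@xRatio * p@irisR; b <- p@yRatio * p@irisR
  expect_lt(abs(sum(m) - pi * a * b) / (pi * a * b), 0.01)

  # rotating 90 degrees with swapped semi-axes reproduces the mask
  p90 <- maskParameters(p@pupilX, p@pupilY, p@pupilR, p@irisX, p@irisY,
                        p@irisR, 0, 0, xRatio = p@yRatio, yRatio = p@xRatio,
                        degree = 90)
  expect_identical(rasterizePeriocularMask(p90, c(256, 256)), m)

  # a circle (equal ratios) is rotation invariant
  pc <- maskParameters(128, 128, 10, 128, 128, 40, 0, 0, 1.2, 1.2, 0)
  pc2 <- maskParameters(128, 128, 10, 128, 128, 40, 0, 0, 1.2, 1.2, 37)
  expect_identical(rasterizePeriocularMask(pc, c(256, 256)),
                   rasterizePeriocularMask(pc2, c(256, 256)))
})

test_that("condition pairs bundle aligned binary channels deterministically", {
  p <- sampleParameters(defaultParameterRanges(), seed = 5)
  cp <- makeConditionPair(p, resolution = c(256, 256), frame = c(480, 640))
  expect_s4_class(cp, "ConditionPair")
  expect_identical(dim(irisMask(cp)), dim(periocularMask(cp)))
  expect_true(all(irisMask(cp) %in% c(0L, 1L)))
  cp2 <- makeConditionPair(p, resolution = c(256, 256), frame = c(480, 640))
  expect_identical(irisMask(cp), irisMask(cp2))
  # with clipping, the iris channel is contained in the periocular channel
  cpc <- makeConditionPair(p, resolution = c(128, 128),
                           clipToPeriocular = TRUE)
  expect_identical(sum(irisMask(cpc) == 1L & periocularMask(cpc) == 0L), 0L)
})

test_that("parameter statistics recover location and bounds of samples", {
  one <- fitParameterStatistics(list(centredParams()))
  expect_equal(one$sd, rep(0, 11))
  expect_equal(one$average, one$min)
  expect_equal(one$average, one$max)

  p1 <- maskParameters(310, 240, 40, 320, 240, 100)
  p2 <- maskParameters(330, 240, 40, 320, 240, 100)
  two <- fitParameterStatistics(list(p1, p2))
  expect_equal(two$average[two$parameter == "pupilX"], 320)

  draws <- lapply(1:1000, function(s) sampleParameters(defaultParameterRanges(), seed = s))
  st <- fitParameterStatistics(draws)
  # uniform [70, 120]: mean within 3 standard errors of the midpoint
  se <- (120 - 70) / sqrt(12) / sqrt(1000)
  expect_lt(abs(st$average[st$parameter == "irisR"] - 95), 3 * se)
  expect_gte(st$min[st$parameter == "irisR"], 70)
  expect_lte(st$max[st$parameter == "irisR"], 120)
})

test_that("parameter sets and masks round-trip through CSV and PNG", {
  ps <- lapply(1:4, function(s) sampleParameters(defaultParameterRanges(), seed = s))
  f <- withr::local_tempfile(fileext = ".csv")
  writeParametersCSV(ps, f)
  back <- readParametersCSV(f)
  expect_equal(paramsToVector(back[[2]]), paramsToVector(ps[[2]]))

  m <- rasterizeIrisMask(centredParams(), c(64, 64))
  fp <- withr::local_tempfile(fileext = ".png")
  writeMaskPNG(m, fp)
  expect_identical(readMaskPNG(fp), m)
})
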