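test_that("noiseless textureless renders are piecewise constant at 4 levels", {
  cfg <- renderConfig(textureAmp = 0, noiseSd = 0)
  img <- renderEye(centredParams(), cfg, c(64, 64), seed = 1)
  expect_true(all(img >= 0 & img <= 1))
  lv <- sort(unique(as.vector(img)))
  expect_identical(lv, sort(c(cfg@pupil, cfg@iris, cfg@sclera, cfg@skin)))
})

test_that("rendering is deterministic given a seed and darker inside the iris", {
  p <- sampleParameters(toyRanges(), seed = 3)
  a <- renderEye(p, renderConfig(), c(64, 64), seed = 9)
  b <- renderEye(p, renderConfig(), c(64, 64), seed = 9)
  expect_identical(a, b)
  cp <- makeConditionPair(p, c(64, 64), clipToPeriocular = TRUE)
  inside <- mean(a[irisMask(cp) == 1L])
  outside <- mean(a[periocularMask(cp) == 0L])
  expect_lt(inside, outside)
})

test_that("glasses mode adds bright glare pixels", {
  p <- centredParams()
  plain <- renderEye(p, renderConfig(noiseSd = 0), c(64, 64), seed = 1)
  glare <- renderEye(p, renderConfig(noiseSd = 0, glasses = TRUE), c(64, 64),
                     seed = 1)
  expect_gt(sum(glare == 1), sum(plain == 1))
})

test_that("intensity thresholding recovers the iris label on noiseless renders", {
  ranges <- toyRanges()
  cfg <- renderConfig(noiseSd = 0)
  for (s in 1:5) {
    p <- sampleParameters(ranges, seed = s)
    img <- renderEye(p, cfg, c(64, 64), seed = s)
    truth <- irisMask(makeConditionPair(p, c(64, 64), clipToPeriocular = TRUE))
    # iris band lies strictly between the pupil and the skin/sclera levels
    thresh <- (img > (cfg@pupil + cfg@iris) / 2) &
      (img < (cfg@iris + cfg@skin) / 2)
    expect_gte(iouBinary(thresh * 1L, truth), 0.95)
  }
})

test_that("rendered datasets are aligned, complete, and reproducible from the manifest", {
  dir <- withr::local_tempdir()
  ds <- renderDataset(10, toyRanges(), renderConfig(), c(64, 64), seed = 21,
                      dir = dir)
  expect_identical(dim(ds$images), c(64L, 64L, 10L))
  expect_length(list.files(dir, pattern = "^img_.*png$"), 10L)
  expect_length(list.files(dir, pattern = "^(iris|peri)_.*png$"), 20L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  # masks re-rasterized from manifest parameters equal the stored masks
  man <- read.csv(file.path(dir, "manifest.csv"))
  for (i in c(1, 6, 10)) {
    p <- vectorToParams(unlist(man[i, maskParameterNames()]))
    cp <- makeConditionPair(p, c(64, 64), clipToPeriocular = TRUE)
    expect_identical(irisMask(cp), readMaskPNG(file.path(dir, sprintf("iris_%04d.png", i))))
    expect_identical(periocularMask(cp), readMaskPNG(file.path(dir, sprintf("peri_%04d.png", i))))
  }

  # distinct seeds give distinct parameter draws
  ds2 <- renderDataset(10, toyRanges(), renderConfig(), c(64, 64), seed = 22)
  expect_false(any(ds2$manifest$pupilX %in% ds$manifest$pupilX))
})
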