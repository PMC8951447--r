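# Independent brute-force oracles used to pin down expected values.
# These deliberately use naive per-pixel / per-element loops, not the
# package's vectorised implementations.

# count pixel centres (0-based) inside the annulus, looping every pixel
oracleAnnulusCount <- function(params, height, width) {
  n <- 0L
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      x <- c - 1; y <- r - 1
      dIris <- (x - params@irisX)^2 + (y - params@irisY)^2
      dPupil <- (x - params@pupilX)^2 + (y - params@pupilY)^2
      if (dIris <= params@irisR^2 && dPupil >= params@pupilR^2) n <- n + 1L
    }
  }
  n
}

oracleEllipseCount <- function(params, height, width) {
  cx <- params@irisX + params@xOffset
  cy <- params@irisY + params@yOffset
  a <- params@xRatio * params@irisR
  b <- params@yRatio * params@irisR
  th <- params@degree * pi / 180
  n <- 0L
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      x <- c - 1; y <- r - 1
      u <- cos(th) * (x - cx) + sin(th) * (y - cy)
      v <- -sin(th) * (x - cx) + cos(th) * (y - cy)
      if ((u / a)^2 + (v / b)^2 <= 1) n <- n + 1L
    }
  }
  n
}

# confusion matrix by explicit per-pixel enumeration
oracleConfusion <- function(pred, true, k) {
  m <- matrix(0L, k, k)
  for (i in seq_along(pred))
    m[true[i] + 1L, pred[i] + 1L] <- m[true[i] + 1L, pred[i] + 1L] + 1L
  m
}

# metric formulas written as direct loops over classes
oracleMetrics <- function(cm) {
  k <- nrow(cm); tot <- sum(cm)
  pa <- sum(diag(cm)) / tot
  recalls <- c(); ious <- c(); fw <- 0
  for (i in seq_len(k)) {
    gt <- sum(cm[i, ])
    if (gt > 0) {
      recalls <- c(recalls, cm[i, i] / gt)
      u <- sum(cm[i, ]) + sum(cm[, i]) - cm[i, i]
      ious <- c(ious, cm[i, i] / u)
      fw <- fw + gt / tot * cm[i, i] / u
    }
  }
  c(PA = pa, mPA = mean(recalls), mIoU = mean(ious), FWIoU = fw)
}

# summed cross-entropy by triple loop
oracleFcnLoss <- function(P, Q) {
  d <- dim(P); s <- 0
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        s <- s - Q[i, j, k] * log(max(P[i, j, k], 1e-12))
  s
}

# Frechet distance via eigendecomposition of the (generally non-symmetric)
# product Sr %*% Sg -- an independent route to the matrix square root
oracleFid <- function(mu1, S1, mu2, S2) {
  e <- eigen(S1 %*% S2)
  sq <- sum(sqrt(pmax(Re(e$values), 0)))
  sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * sq
}

iouBinary <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) 1 else inter / union
}

# small shared fixtures
toyRanges <- function(side = 64) scaleRanges(defaultParameterRanges(), side, side)

centredParams <- function(side = 64) {
  maskParameters(pupilX = side / 2, pupilY = side / 2, pupilR = side / 10,
                 irisX = side / 2, irisY = side / 2, irisR = side / 4,
                 xOffset = 0, yOffset = 0, xRatio = 1.6, yRatio = 0.9,
                 degree = 0)
}

# desk-scale training presets (calibrated once; see the methods vignette)
toyGanConfig <- function(seed) {
  ganTrainingConfig(lr = 1e-3, batchSize = 16, iterations = 200,
                    baseWidth = 16, discBaseWidth = 8,
                    nonSaturating = FALSE, generatorDropout = 0, seed = seed)
}
toySegConfig <- function(seed) {
  segConfig(classes = 2, lr = 1e-3, batchSize = 8, epochs = 10,
            baseWidth = 8, seed = seed)
}
toyAugment <- function(ds, seed) {
  acfg <- augmentationConfig(flipProb = 0.5, cropSize = c(56, 56),
                             outputSize = c(64, 64))
  augmentDataset(ds$images, ds$irisMasks, ds$periocularMasks, acfg,
                 copies = 1, seed = seed)
}
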