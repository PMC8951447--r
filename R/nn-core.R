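# Layer primitives for the convolutional networks. Activations are 4-d
# arrays dim (H, W, C, N); all convolutions are kernel 4, stride 2, pad 1,
# so spatial size exactly halves (conv) or doubles (transposed conv).

NN_KERNEL <- 4L
NN_STRIDE <- 2L
NN_PAD <- 1L

convF <- function(x, W, b) nn_conv_fwd(x, W, b, NN_STRIDE, NN_PAD)
convB <- function(x, W, g) nn_conv_bwd(x, W, g, NN_STRIDE, NN_PAD)
tconvF <- function(x, W, b) nn_tconv_fwd(x, W, b, NN_STRIDE, NN_PAD)
tconvB <- function(x, W, g) nn_tconv_bwd(x, W, g, NN_STRIDE, NN_PAD)

as4d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  else if (length(dim(x)) != 4L) stop("expected a 2-d/3-d/4-d array")
  x
}

# instance normalization: per sample, per channel over spatial positions
inormF <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, HW)
  mu <- colMeans(xm)
  v <- pmax(colMeans(xm * xm) - mu^2, 0)
  sdv <- sqrt(v + eps)
  xhat <- (xm - rep(mu, each = HW)) / rep(sdv, each = HW)
  ge <- rep(rep(gamma, N), each = HW)
  y <- xhat * ge + rep(rep(beta, N), each = HW)
  dim(y) <- d
  list(y = y, xhat = xhat, sdv = sdv, ge = ge, C = C, N = N)
}

inormB <- function(gy, cache) {
  d <- dim(gy); HW <- d[1] * d[2]
  gm <- matrix(gy, HW)
  gxhat <- gm * cache$ge
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * cache$xhat)
  gx <- (gxhat - rep(m1, each = HW) - cache$xhat * rep(m2, each = HW)) /
    rep(cache$sdv, each = HW)
  dim(gx) <- d
  ggamma <- rowSums(matrix(colSums(gm * cache$xhat), cache$C, cache$N))
  gbeta <- rowSums(matrix(colSums(gm), cache$C, cache$N))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

sigmoidF <- function(z) 1 / (1 + exp(-z))

# channel-wise softmax over dim 3
softmaxC <- function(z) {
  d <- dim(z); K <- d[3]
  m <- matrix(aperm(z, c(1, 2, 4, 3)), ncol = K)
  mx <- m[, 1]
  if (K > 1) for (k in 2:K) mx <- pmax(mx, m[, k])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  aperm(array(p, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[c(1, 2, 4)], db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

convLayer <- function(cin, cout, norm = TRUE, initSd = 0.02) {
  list(W = array(rnorm(NN_KERNEL * NN_KERNEL * cin * cout, 0, initSd),
                 c(NN_KERNEL, NN_KERNEL, cin, cout)),
       b = rep(0, cout),
       gamma = if (norm) rep(1, cout) else NULL,
       beta = if (norm) rep(0, cout) else NULL,
       cin = cin, cout = cout)
}

tconvLayer <- function(cin, cout, norm = TRUE, dropout = 0, initSd = 0.02) {
  list(W = array(rnorm(NN_KERNEL * NN_KERNEL * cout * cin, 0, initSd),
                 c(NN_KERNEL, NN_KERNEL, cout, cin)),
       b = rep(0, cout),
       gamma = if (norm) rep(1, cout) else NULL,
       beta = if (norm) rep(0, cout) else NULL,
       cin = cin, cout = cout, dropout = dropout)
}

checkNetInput <- function(x, depth, inChannels) {
  d <- dim(x)
  if (d[3] != inChannels)
    stop("input has ", d[3], " channels; network expects ", inChannels)
  if (d[1] %% (2^depth) != 0 || d[2] %% (2^depth) != 0)
    stop("input resolution ", d[1], "x", d[2],
         " is not divisible by 2^depth = ", 2^depth)
  invisible(d)
}

# ---- U-Net (encoder-decoder with skip connections) ----

unetForward <- function(net, x, train = FALSE) {
  x <- as4d(x)
  checkNetInput(x, net$depth, net$inChannels)
  D <- net$depth
  encA <- vector("list", D)
  cEnc <- vector("list", D)
  cDec <- vector("list", D)
  a <- x
  for (l in seq_len(D)) {
    ly <- net$enc[[l]]
    z <- convF(a, ly$W, ly$b)
    cc <- list(x = a)
    h <- z
    if (!is.null(ly$gamma) && prod(dim(z)[1:2]) > 1L) {
      ino <- inormF(z, ly$gamma, ly$beta)
      h <- ino$y
      cc$ino <- ino[c("xhat", "sdv", "ge", "C", "N")]
    }
    pos <- h > 0
    a <- h * (pos + 0.2 * (!pos))  # LeakyReLU(0.2)
    cc$pos <- pos
    cEnc[[l]] <- cc
    encA[[l]] <- a
  }
  u <- a
  for (l in seq_len(D)) {
    ly <- net$dec[[l]]
    inp <- if (l == 1L) u else catChannels(u, encA[[D - l + 1L]])
    z <- tconvF(inp, ly$W, ly$b)
    cc <- list(x = inp)
    if (l < D) {
      h <- z
      if (!is.null(ly$gamma) && prod(dim(z)[1:2]) > 1L) {
        ino <- inormF(z, ly$gamma, ly$beta)
        h <- ino$y
        cc$ino <- ino[c("xhat", "sdv", "ge", "C", "N")]
      }
      if (train && ly$dropout > 0) {
        mask <- array((runif(length(h)) >= ly$dropout) / (1 - ly$dropout),
                      dim(h))
        h <- h * mask
        cc$mask <- mask
      }
      pos <- h > 0
      u <- h * pos  # ReLU
      cc$pos <- pos
    } else {
      u <- switch(net$head,
                  sigmoid = sigmoidF(z),
                  softmax = softmaxC(z),
                  linear = z)
      cc$y <- u
    }
    cDec[[l]] <- cc
  }
  list(y = u, cache = list(enc = cEnc, dec = cDec))
}

# gy: gradient wrt the network output; for a softmax head pass gzLast
# (gradient wrt pre-softmax logits) instead.
unetBackward <- function(net, cache, gy = NULL, gzLast = NULL) {
  D <- net$depth
  gDec <- vector("list", D)
  gEncL <- vector("list", D)
  skipG <- vector("list", D)
  gu <- NULL
  for (l in D:1) {
    ly <- net$dec[[l]]
    cc <- cache$dec[[l]]
    if (l == D) {
      gz <- if (!is.null(gzLast)) gzLast
      else if (net$head == "sigmoid") gy * cc$y * (1 - cc$y)
      else if (net$head == "linear") gy
      else stop("softmax head requires gzLast (logit gradient)")
    } else {
      g <- gu * cc$pos
      if (!is.null(cc$mask)) g <- g * cc$mask
      if (!is.null(cc$ino)) {
        ib <- inormB(g, cc$ino)
        gz <- ib$gx
      } else gz <- g
    }
    tb <- tconvB(cc$x, ly$W, gz)
    gDec[[l]] <- list(W = tb$gw, b = tb$gb,
                      gamma = if (l < D && !is.null(cc$ino)) ib$ggamma else NULL,
                      beta = if (l < D && !is.null(cc$ino)) ib$gbeta else NULL)
    gin <- tb$gx
    if (l == 1L) {
      skipG[[D]] <- if (is.null(skipG[[D]])) gin else skipG[[D]] + gin
    } else {
      cu <- net$dec[[l - 1L]]$cout
      gu <- gin[, , seq_len(cu), , drop = FALSE]
      gs <- gin[, , cu + seq_len(dim(gin)[3] - cu), , drop = FALSE]
      k <- D - l + 1L
      skipG[[k]] <- if (is.null(skipG[[k]])) gs else skipG[[k]] + gs
    }
  }
  g <- NULL
  for (l in D:1) {
    if (!is.null(skipG[[l]])) g <- if (is.null(g)) skipG[[l]] else g + skipG[[l]]
    ly <- net$enc[[l]]
    cc <- cache$enc[[l]]
    gh <- g * (cc$pos + 0.2 * (!cc$pos))
    if (!is.null(cc$ino)) {
      ib <- inormB(gh, cc$ino)
      gz <- ib$gx
    } else gz <- gh
    cb <- convB(cc$x, ly$W, gz)
    gEncL[[l]] <- list(W = cb$gw, b = cb$gb,
                       gamma = if (!is.null(cc$ino)) ib$ggamma else NULL,
                       beta = if (!is.null(cc$ino)) ib$gbeta else NULL)
    g <- cb$gx
  }
  list(enc = gEncL, dec = gDec, gx = g)
}

# ---- plain convolutional chain (patch discriminator) ----

chainForward <- function(net, x) {
  x <- as4d(x)
  if (dim(x)[3] != net$inChannels)
    stop("input has ", dim(x)[3], " channels; network expects ", net$inChannels)
  L <- length(net$layers)
  caches <- vector("list", L)
  shapes <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    z <- convF(a, ly$W, ly$b)
    shapes[[l]] <- dim(z)[1:2]
    cc <- list(x = a)
    if (l < L) {
      h <- z
      if (!is.null(ly$gamma) && prod(dim(z)[1:2]) > 1L) {
        ino <- inormF(z, ly$gamma, ly$beta)
        h <- ino$y
        cc$ino <- ino[c("xhat", "sdv", "ge", "C", "N")]
      }
      pos <- h > 0
      a <- h * (pos + 0.2 * (!pos))
      cc$pos <- pos
    } else {
      a <- sigmoidF(z)
      cc$y <- a
    }
    caches[[l]] <- cc
  }
  list(y = a, cache = caches, shapes = shapes)
}

# pass gy (wrt sigmoid output) or gzLast (wrt final pre-sigmoid logits)
chainBackward <- function(net, cache, gy = NULL, gzLast = NULL) {
  L <- length(net$layers)
  grads <- vector("list", L)
  g <- NULL
  for (l in L:1) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    if (l == L) {
      gz <- if (!is.null(gzLast)) gzLast else gy * cc$y * (1 - cc$y)
    } else {
      gh <- g * (cc$pos + 0.2 * (!cc$pos))
      if (!is.null(cc$ino)) {
        ib <- inormB(gh, cc$ino)
        gz <- ib$gx
      } else gz <- gh
    }
    cb <- convB(cc$x, ly$W, gz)
    grads[[l]] <- list(W = cb$gw, b = cb$gb,
                       gamma = if (l < L && !is.null(cc$ino)) ib$ggamma else NULL,
                       beta = if (l < L && !is.null(cc$ino)) ib$gbeta else NULL)
    g <- cb$gx
  }
  list(layers = grads, gx = g)
}

# ---- Adam ----

NN_PARAM_NAMES <- c("W", "b", "gamma", "beta")

adamZeros <- function(p) {
  if (is.list(p)) {
    nms <- names(p)
    out <- vector("list", length(p))
    names(out) <- nms
    for (i in seq_along(p)) {
      if (is.list(p[[i]])) out[[i]] <- adamZeros(p[[i]])
      else if (!is.null(nms) && nms[i] %in% NN_PARAM_NAMES &&
               is.numeric(p[[i]])) out[[i]] <- p[[i]] * 0
      else out[i] <- list(NULL)
    }
    out
  } else NULL
}

adamState <- function(params) list(m = adamZeros(params), v = adamZeros(params), t = 0L)

adamApply <- function(p, g, m, v, lr, b1, b2, t, eps = 1e-8) {
  nms <- names(p)
  for (i in seq_along(p)) {
    if (is.list(p[[i]])) {
      if (is.null(g[[i]])) next
      r <- adamApply(p[[i]], g[[i]], m[[i]], v[[i]], lr, b1, b2, t, eps)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    } else if (!is.null(nms) && nms[i] %in% NN_PARAM_NAMES &&
               is.numeric(p[[i]]) && !is.null(g[[nms[i]]])) {
      gi <- g[[nms[i]]]
      m[[i]] <- b1 * m[[i]] + (1 - b1) * gi
      v[[i]] <- b2 * v[[i]] + (1 - b2) * gi * gi
      mh <- m[[i]] / (1 - b1^t)
      vh <- v[[i]] / (1 - b2^t)
      p[[i]] <- p[[i]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(p = p, m = m, v = v)
}

adamStep <- function(params, grads, state, lr, beta1, beta2) {
  state$t <- state$t + 1L
  r <- adamApply(params, grads, state$m, state$v, lr, beta1, beta2, state$t)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}
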