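# Native 1-D neural-network engine used by the CNN and ResNet regressors.
# Batches are arrays (batch, length, channels); convolutions run as im2col
# matrix products against BLAS, gradients are hand-derived, optimization is
# Adam, and all randomness (init, shuffling) flows from one seed, so
# training is bit-deterministic on CPU.

# ---- im2col helpers --------------------------------------------------------

padLen <- function(L, K, stride) {
  Lout <- ceiling(L / stride)
  max((Lout - 1L) * stride + K - L, 0L)
}

# ---- layer constructors (environments carry params + Adam state) -----------

newConv <- function(K, Cin, Cout, stride = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$K <- as.integer(K); e$Cin <- Cin; e$Cout <- Cout
  e$stride <- as.integer(stride)
  e$W <- matrix(stats::rnorm(K * Cin * Cout, 0, sqrt(2 / (K * Cin))),
                K * Cin, Cout)
  e$b <- numeric(Cout)
  e
}

newDense <- function(Fin, Fout, outScale = 1) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$Fin <- Fin; e$Fout <- Fout
  e$W <- matrix(stats::rnorm(Fin * Fout, 0, outScale * sqrt(2 / Fin)),
                Fin, Fout)
  e$b <- numeric(Fout)
  e
}

newBatchNorm <- function(C, momentum = 0.9, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "bnorm"; e$C <- C; e$momentum <- momentum; e$eps <- eps
  e$gamma <- rep(1, C); e$beta <- numeric(C)
  e$runMean <- numeric(C); e$runVar <- rep(1, C)
  e
}

newRelu <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "relu"; e
}

newMaxPool <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "maxpool"; e
}

newFlatten <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "flatten"; e
}

newGlobalAvgPool <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "gap"; e
}

newResBlock <- function(Cin, Cout, stride = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "resblock"
  e$main <- list(newConv(3L, Cin, Cout, stride), newBatchNorm(Cout),
                 newRelu(), newConv(3L, Cout, Cout, 1L), newBatchNorm(Cout))
  # identity shortcut when shape is preserved (adds no parameters);
  # 1x1 projection + BN when width or length changes
  e$project <- (Cin != Cout) || (stride != 1L)
  if (e$project)
    e$shortcut <- list(newConv(1L, Cin, Cout, stride), newBatchNorm(Cout))
  e
}

# ---- forward / backward ----------------------------------------------------

layerForward <- function(e, x, training) {
  switch(e$type,
    conv = {
      d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
      pl <- padLen(L, e$K, e$stride) %/% 2L
      Lout <- ceiling(L / e$stride)
      P <- cpp_im2col(x, B, L, C, e$K, e$stride, pl, Lout)
      y <- P %*% e$W
      y <- y + rep(e$b, each = B * Lout)
      if (training) { e$P <- P; e$inDim <- d; e$pl <- pl; e$Lout <- Lout }
      dim(y) <- c(B, Lout, e$Cout)
      y
    },
    dense = {
      y <- x %*% e$W + rep(e$b, each = nrow(x))
      if (training) e$x <- x
      y
    },
    bnorm = {
      d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
      xm <- x; dim(xm) <- c(B * L, C)
      if (training) {
        r <- cpp_bn_fwd(xm, e$gamma, e$beta, e$eps)
        e$runMean <- e$momentum * e$runMean + (1 - e$momentum) * r$mu
        e$runVar <- e$momentum * e$runVar + (1 - e$momentum) * r$var
        e$xhat <- r$xhat; e$istd <- r$istd; e$dims <- d
        y <- r$y
      } else {
        n <- B * L
        scale <- e$gamma / sqrt(e$runVar + e$eps)
        y <- (xm - rep(e$runMean, each = n)) * rep(scale, each = n) +
          rep(e$beta, each = n)
      }
      dim(y) <- d
      y
    },
    relu = {
      y <- x * (x > 0)
      if (training) e$y <- y
      y
    },
    maxpool = {
      d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
      if (L < 2L) stop("input too short for max pooling")
      r <- cpp_maxpool_fwd(x, B, L, C)
      if (training) { e$takeA <- r$takeA; e$inDim <- d }
      r$y
    },
    flatten = {
      d <- dim(x)
      if (training) e$inDim <- d
      dim(x) <- c(d[1], d[2] * d[3])
      x
    },
    gap = {
      d <- dim(x)
      if (training) e$inDim <- d
      ap <- aperm(x, c(2L, 1L, 3L))
      dim(ap) <- c(d[2], d[1] * d[3])
      y <- colMeans(ap)
      dim(y) <- c(d[1], d[3])
      y
    },
    resblock = {
      h <- x
      for (l in e$main) h <- layerForward(l, h, training)
      s <- x
      if (e$project) for (l in e$shortcut) s <- layerForward(l, s, training)
      pre <- h + s
      if (training) e$preMask <- pre > 0
      pre * (pre > 0)
    },
    stop("unknown layer type ", e$type))
}

layerBackward <- function(e, dy) {
  switch(e$type,
    conv = {
      d <- e$inDim; B <- d[1]; L <- d[2]; C <- d[3]
      Lout <- e$Lout
      dYm <- dy; dim(dYm) <- c(B * Lout, e$Cout)
      e$dW <- crossprod(e$P, dYm)
      e$db <- colSums(dYm)
      dP <- tcrossprod(dYm, e$W)               # (B*Lout) x (K*C)
      dx <- cpp_col2im(dP, B, L, C, e$K, e$stride, e$pl, Lout)
      e$P <- NULL
      dx
    },
    dense = {
      e$dW <- crossprod(e$x, dy)
      e$db <- colSums(dy)
      dx <- dy %*% t(e$W)
      e$x <- NULL
      dx
    },
    bnorm = {
      d <- e$dims; B <- d[1]; L <- d[2]; C <- d[3]
      dym <- dy; dim(dym) <- c(B * L, C)
      r <- cpp_bn_bwd(dym, e$xhat, e$gamma, e$istd)
      e$dgamma <- r$dgamma
      e$dbeta <- r$dbeta
      dx <- r$dx
      dim(dx) <- d
      e$xhat <- NULL
      dx
    },
    relu = dy * (e$y > 0),
    maxpool = {
      d <- e$inDim
      cpp_maxpool_bwd(dy, e$takeA, d[1], d[2], d[3])
    },
    flatten = {
      dim(dy) <- e$inDim
      dy
    },
    gap = {
      d <- e$inDim
      aperm(array(dy / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
    },
    resblock = {
      dpre <- dy * e$preMask
      dh <- dpre
      for (l in rev(e$main)) dh <- layerBackward(l, dh)
      ds <- dpre
      if (e$project) for (l in rev(e$shortcut)) ds <- layerBackward(l, ds)
      dh + ds
    },
    stop("unknown layer type ", e$type))
}

netForward <- function(layers, x, training = FALSE) {
  for (e in layers) x <- layerForward(e, x, training)
  x
}

netBackward <- function(layers, dy) {
  for (e in rev(layers)) dy <- layerBackward(e, dy)
  invisible(dy)
}

# Collect every parameterized layer environment (recursing into blocks).
paramLayers <- function(layers) {
  out <- list()
  for (e in layers) {
    if (e$type == "resblock") {
      out <- c(out, paramLayers(e$main))
      if (e$project) out <- c(out, paramLayers(e$shortcut))
    } else if (e$type %in% c("conv", "dense", "bnorm")) {
      out <- c(out, list(e))
    }
  }
  out
}

adamInit <- function(layers) {
  for (e in paramLayers(layers)) {
    nms <- if (e$type == "bnorm") c("gamma", "beta") else c("W", "b")
    e$adam <- lapply(stats::setNames(nms, nms), function(nm)
      list(m = e[[nm]] * 0, v = e[[nm]] * 0))
  }
}

adamStep <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  lrEff <- lr * sqrt(b2t) / b1t          # fold bias corrections into the step
  epsEff <- eps * sqrt(b2t)
  for (e in paramLayers(layers)) {
    nms <- if (e$type == "bnorm") c("gamma", "beta") else c("W", "b")
    gnms <- if (e$type == "bnorm") c("dgamma", "dbeta") else c("dW", "db")
    for (i in seq_along(nms)) {
      st <- e$adam[[nms[i]]]
      cpp_adam(e[[nms[i]]], st$m, st$v, e[[gnms[i]]],
               beta1, beta2, lrEff, epsEff)
    }
  }
}

# ---- architectures ---------------------------------------------------------

# conv(64) -> pool -> conv(128) -> pool -> conv(256) -> flatten ->
# dense(64) -> dense(1); ReLU after each conv and the first dense layer.
buildCnn1d <- function(inputLen, convChannels = c(64L, 128L, 256L),
                       denseUnits = 64L, stemKernel = 7L, kernel = 3L) {
  if (inputLen %/% 4L < 1L)
    stop(sprintf("input length %d too short for two pooling halvings",
                 inputLen))
  L1 <- inputLen %/% 2L; L2 <- L1 %/% 2L
  layers <- list(
    newConv(stemKernel, 1L, convChannels[1]), newRelu(), newMaxPool(),
    newConv(kernel, convChannels[1], convChannels[2]), newRelu(),
    newMaxPool(),
    newConv(kernel, convChannels[2], convChannels[3]), newRelu(),
    newFlatten(),
    newDense(L2 * convChannels[3], denseUnits), newRelu(),
    newDense(denseUnits, 1L, outScale = 0.1))
  layers
}

# 1-D ResNet-18: stem conv (stride 2) + max pool, four stages of two basic
# blocks (16 convolutions inside the blocks), global average pool, linear
# head. Stage widths default to a quarter of the image-classification
# widths — the 1-D adaptation for short spectral inputs.
buildResNet1d <- function(inputLen, widths = c(32L, 64L, 128L, 256L),
                          stemKernel = 7L) {
  len <- ceiling(inputLen / 2) %/% 2L          # after stem conv + pool
  if (len < 1L)
    stop(sprintf("input length %d too short for the ResNet stem", inputLen))
  layers <- list(newConv(stemKernel, 1L, widths[1], stride = 2L),
                 newBatchNorm(widths[1]), newRelu(), newMaxPool())
  cin <- widths[1]
  for (s in seq_along(widths)) {
    stride <- if (s == 1L) 1L else 2L
    layers <- c(layers, list(newResBlock(cin, widths[s], stride),
                             newResBlock(widths[s], widths[s], 1L)))
    cin <- widths[s]
  }
  c(layers, list(newGlobalAvgPool(), newDense(cin, 1L, outScale = 0.1)))
}

# ---- training loop ---------------------------------------------------------

# Train a network on (x, y) with Adam + MSE. x is standardized per channel
# and y centered/scaled internally; scalers are stored on the handle.
trainNetwork <- function(x, y, build, lr, epochs, batchSize, seed) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n == 0L) stop("empty training set")
  if (anyNA(x) || anyNA(y)) stop("training data contain missing values")
  mX <- colMeans(x); sdX <- apply(x, 2L, stats::sd); sdX[sdX == 0] <- 1
  mY <- mean(y); sdY <- stats::sd(y); if (is.na(sdY) || sdY == 0) sdY <- 1
  xs <- sweep(sweep(x, 2L, mX), 2L, sdX, "/")
  ys <- (y - mY) / sdY
  withLocalSeed(seed, {
    layers <- build(ncol(x))
    adamInit(layers)
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        xb <- xs[idx, , drop = FALSE]
        dim(xb) <- c(length(idx), ncol(x), 1L)
        yb <- ys[idx]
        out <- netForward(layers, xb, training = TRUE)
        res <- drop(out) - yb
        dy <- matrix(2 * res / length(idx), ncol = 1L)
        netBackward(layers, dy)
        step <- step + 1L
        adamStep(layers, lr, step)
      }
    }
    list(layers = layers, meanX = mX, sdX = sdX, meanY = mY, sdY = sdY,
         nChannels = ncol(x))
  })
}

predictNetwork <- function(net, x) {
  x <- as.matrix(x)
  if (ncol(x) != net$nChannels)
    stop(sprintf("x has %d channels, network was trained with %d",
                 ncol(x), net$nChannels))
  xs <- sweep(sweep(x, 2L, net$meanX), 2L, net$sdX, "/")
  dim(xs) <- c(nrow(x), net$nChannels, 1L)
  out <- netForward(net$layers, xs, training = FALSE)
  drop(out) * net$sdY + net$meanY
}
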