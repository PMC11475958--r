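# Partial least squares regression (PLS1) via the SIMPLS algorithm.
# Used as the fitness engine of the genetic wavelength selector and for
# coefficient-based wavelength importance; deliberately lightweight so it
# can be called tens of thousands of times inside the GA loop.

#' Fit a univariate PLS regression (SIMPLS)
#'
#' @param x predictor matrix (samples x channels).
#' @param y numeric response vector.
#' @param ncomp number of latent components; silently capped at the
#'   predictor rank bound `min(ncol(x), nrow(x) - 1)` and truncated with a
#'   warning if the score space is exhausted earlier.
#' @param scale standardize predictors to unit variance before fitting
#'   (coefficients are then on the standardized scale, comparable across
#'   channels).
#' @return an object of class "plsFit" with elements `coefficients`
#'   (per-channel, on the input or standardized scale as requested),
#'   `intercept`, `ncomp` (components actually used), `meanX`, `scaleX`,
#'   `meanY`.
#' @examples
#' x <- matrix(rnorm(100), 20, 5)
#' y <- x[, 2] - 0.5 * x[, 4]
#' fit <- plsFit(x, y, ncomp = 3)
#' max(abs(plsPredict(fit, x) - y)) < 1e-8
#' @export
plsFit <- function(x, y, ncomp = 2L, scale = FALSE) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n != length(y)) stop("x rows and y length differ")
  if (n < 2L || p < 1L) stop("need at least 2 samples and 1 predictor")
  ncomp <- max(1L, min(as.integer(ncomp), p, n - 1L))
  mX <- colMeans(x)
  sX <- rep(1, p)
  if (scale) {
    sX <- apply(x, 2L, stats::sd)
    sX[sX == 0] <- 1
  }
  X <- sweep(sweep(x, 2L, mX), 2L, sX, "/")
  mY <- mean(y)
  yc <- y - mY
  if (all(yc == 0)) {
    return(structure(list(coefficients = numeric(p), intercept = mY,
                          ncomp = 0L, meanX = mX, scaleX = sX, meanY = mY),
                     class = "plsFit"))
  }
  s <- crossprod(X, yc)                       # p x 1
  R <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    r <- s
    tt <- X %*% r
    nt <- sqrt(sum(tt^2))
    if (nt < 1e-12) break                     # score space exhausted
    tt <- tt / nt; r <- r / nt
    pp <- crossprod(X, tt)                    # loading
    qq <- sum(yc * tt)
    v <- pp
    if (a > 0L) {
      Vk <- V[, seq_len(a), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, pp)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    a <- a + 1L
    R[, a] <- r; Q[a] <- qq; V[, a] <- v
  }
  if (a == 0L)
    stop("PLS could not extract any component (degenerate predictors)")
  if (a < ncomp)
    warning(sprintf("PLS components reduced from %d to %d (rank limit)",
                    ncomp, a))
  beta <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  structure(list(coefficients = drop(beta), intercept = mY,
                 ncomp = a, meanX = mX, scaleX = sX, meanY = mY),
            class = "plsFit")
}

#' Predict from a fitted PLS regression
#'
#' @param fit a [plsFit()] object.
#' @param x predictor matrix with the same channel count used in fitting.
#' @return numeric vector of predictions.
#' @export
plsPredict <- function(fit, x) {
  stopifnot(inherits(fit, "plsFit"))
  x <- as.matrix(x)
  if (ncol(x) != length(fit$meanX))
    stop(sprintf("x has %d channels, model was fitted with %d",
                 ncol(x), length(fit$meanX)))
  X <- sweep(sweep(x, 2L, fit$meanX), 2L, fit$scaleX, "/")
  drop(X %*% fit$coefficients) + fit$intercept
}

# Deterministic k-fold assignment: a seeded shuffle of rep(1:k).
cvFolds <- function(n, k, seed) {
  k <- max(2L, min(as.integer(k), n))
  withLocalSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

# k-fold cross-validated MSE of a PLS fit on the given (x, y).
plsCvMse <- function(x, y, ncomp, folds) {
  k <- max(folds)
  sse <- 0
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    nc <- min(ncomp, ncol(x), length(tr) - 1L)
    fit <- suppressWarnings(plsFit(x[tr, , drop = FALSE], y[tr], nc))
    pred <- plsPredict(fit, x[te, , drop = FALSE])
    sse <- sse + sum((y[te] - pred)^2)
  }
  sse / length(y)
}
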