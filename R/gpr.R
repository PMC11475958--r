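# Gaussian-process calibration of prediction uncertainty. A Matern 5/2 GP
# with Gaussian observation noise maps model predictions to reference
# values, Y = f(x) + eps, eps ~ N(0, sn2); hyperparameters are optimized by
# marginal-likelihood maximization and 95% prediction intervals follow from
# the posterior predictive mean and SD (noise variance included, so the
# interval covers observations, not just the latent function).

matern52 <- function(x1, x2, lengthScale, signalVariance) {
  r <- abs(outer(x1, x2, "-")) / lengthScale
  s5 <- sqrt(5) * r
  signalVariance * (1 + s5 + (5 / 3) * r^2) * exp(-s5)
}

# Negative log marginal likelihood at log-parameters (log l, log sf2, log sn2).
gprNegLogLik <- function(logTheta, x, yc) {
  l <- exp(logTheta[1]); sf2 <- exp(logTheta[2]); sn2 <- exp(logTheta[3])
  n <- length(x)
  K <- matern52(x, x, l, sf2)
  diag(K) <- diag(K) + sn2 + 1e-10 * sf2
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian-process calibration (Matern 5/2)
#'
#' Fits `target = f(input) + eps` with a Matern 5/2 kernel and Gaussian
#' noise; the length-scale, signal variance and noise variance are
#' optimized by marginal-likelihood maximization (L-BFGS on log
#' parameters), then the posterior state is precomputed for
#' [predictInterval()]. With many calibration points the hyperparameters
#' are optimized on an evenly spaced (by input order) subsample of 600
#' points for tractability; the posterior always uses every point.
#'
#' @param calibInputs model predictions (numeric vector, length >= 3).
#' @param calibTargets aligned actual values.
#' @return a fitted [GPRCalibration-class].
#' @export
fitGPR <- function(calibInputs, calibTargets) {
  x <- as.numeric(calibInputs); y <- as.numeric(calibTargets)
  n <- length(x)
  if (n != length(y)) stop("inputs and targets differ in length")
  if (n < 3L) stop("need at least 3 calibration points")
  if (anyNA(x) || anyNA(y)) stop("calibration data contain missing values")
  meanY <- mean(y)
  yc <- y - meanY
  sdX <- stats::sd(x); vY <- stats::var(y)
  degenerate <- sdX == 0 || vY == 0
  if (degenerate) {
    warning("degenerate calibration data; noise variance floored at 1e-8")
    l <- max(sdX, 1e-3); sf2 <- max(vY, 1e-8); sn2 <- 1e-8
  } else {
    xo <- x; yo <- yc
    if (n > 600L) {
      keep <- order(x)[unique(round(seq(1, n, length.out = 600L)))]
      xo <- x[keep]; yo <- yc[keep]
    }
    init <- log(c(sdX, vY, 0.1 * vY))
    opt <- stats::optim(init, gprNegLogLik, x = xo, yc = yo,
                        method = "L-BFGS-B",
                        lower = log(c(sdX * 1e-3, vY * 1e-6, vY * 1e-9)),
                        upper = log(c(sdX * 1e3, vY * 1e3, vY * 1e2)))
    l <- exp(opt$par[1]); sf2 <- exp(opt$par[2])
    sn2 <- max(exp(opt$par[3]), 1e-12)
  }
  K <- matern52(x, x, l, sf2)
  diag(K) <- diag(K) + sn2 + 1e-10 * sf2
  ch <- chol(K)
  L <- t(ch)
  alpha <- backsolve(ch, forwardsolve(L, yc))
  new("GPRCalibration", lengthScale = l, signalVariance = sf2,
      noiseVariance = sn2, xTrain = x, yTrain = y, meanY = meanY,
      L = L, alpha = as.numeric(alpha), fitted = TRUE)
}

#' Posterior prediction intervals from a fitted GP calibration
#'
#' Computes the posterior predictive mean and SD at each input; the
#' predictive variance includes the fitted noise variance, and bounds
#' are `mu +/- z * sigma` with z the two-sided normal quantile of the
#' confidence level (1.96 at 95%).
#'
#' @param calib a fitted [GPRCalibration-class].
#' @param inputs model predictions to calibrate.
#' @param confidence nominal coverage level, default 0.95.
#' @return a [PredictionInterval-class].
#' @examples
#' g <- fitGPR(1:20, (1:20) * 0.5)
#' predictInterval(g, c(5.5, 10.5))
#' @export
predictInterval <- function(calib, inputs, confidence = 0.95) {
  stopifnot(is(calib, "GPRCalibration"))
  if (!calib@fitted) stop("calibration has not been fitted")
  xs <- as.numeric(inputs)
  Ks <- matern52(calib@xTrain, xs, calib@lengthScale, calib@signalVariance)
  mu <- drop(crossprod(Ks, calib@alpha)) + calib@meanY
  v <- forwardsolve(calib@L, Ks)
  sig2 <- calib@signalVariance - colSums(v^2) + calib@noiseVariance
  sig <- sqrt(pmax(sig2, 0))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  new("PredictionInterval", mu = mu, sigma = sig,
      lower = mu - z * sig, upper = mu + z * sig,
      confidence = confidence)
}
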