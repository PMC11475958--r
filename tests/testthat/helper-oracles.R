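# Independent reference implementations used as oracles. Deliberately
# written with plain loops and dense algebra, sharing no code with the
# package internals they check.

# Reference max-min selector: every greedy step is resolved by explicit
# enumeration over all candidates (and the seed pair over all pairs),
# ties to the lowest index.
oracleMaxMin <- function(d, nTrain) {
  n <- nrow(d)
  if (nTrain == n) return(seq_len(n))
  bestPair <- c(1L, 2L); bestVal <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > bestVal) { bestVal <- d[i, j]; bestPair <- c(i, j) }
  }
  sel <- bestPair
  while (length(sel) < nTrain) {
    cand <- setdiff(seq_len(n), sel)
    bestC <- cand[1]; bestVal <- -Inf
    for (k in cand) {
      mink <- min(d[k, sel])
      if (mink > bestVal) { bestVal <- mink; bestC <- k }
    }
    sel <- c(sel, bestC)
  }
  sort(sel)
}

# Joint SPXY distance built directly from the definition.
oracleSpxyDist <- function(x, y) {
  n <- nrow(x)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  mdx <- max(dx); mdy <- max(dy)
  (if (mdx > 0) dx / mdx else dx * 0) + (if (mdy > 0) dy / mdy else dy * 0)
}

# Matern 5/2 kernel written out again from its formula.
oracleMatern52 <- function(a, b, l, sf2) {
  K <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    r <- abs(a[i] - b[j]) / l
    K[i, j] <- sf2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  K
}

# Dense-matrix GP posterior (predictive mean and SD including noise),
# evaluated with solve() straight from the posterior formulas.
oracleGpPosterior <- function(xTrain, yTrain, xStar, l, sf2, sn2) {
  mu0 <- mean(yTrain)
  K <- oracleMatern52(xTrain, xTrain, l, sf2) +
    diag(sn2 + 1e-10 * sf2, length(xTrain))
  Ks <- oracleMatern52(xStar, xTrain, l, sf2)
  Kinv <- solve(K)
  mu <- drop(Ks %*% Kinv %*% (yTrain - mu0)) + mu0
  var <- sf2 - diag(Ks %*% Kinv %*% t(Ks)) + sn2
  list(mu = mu, sigma = sqrt(pmax(var, 0)))
}

# Plain k-fold CV MSE of a PLS model, recomputed outside the GA machinery
# (uses the exported plsFit/plsPredict but its own fold loop).
oracleCvMse <- function(x, y, ncomp, folds) {
  err <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- suppressWarnings(
      plsFit(x[tr, , drop = FALSE], y[tr],
             min(ncomp, ncol(x), sum(tr) - 1)))
    err <- c(err, (y[!tr] - plsPredict(fit, x[!tr, , drop = FALSE]))^2)
  }
  mean(err)
}

# Small deterministic spectra fixture shared across tests.
smallSpectra <- function(n = 30, seed = 11, ...) {
  simulateSpectra(generatorConfig(nSamples = n, seed = seed, ...))
}
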