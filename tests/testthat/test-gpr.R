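test_that("a noise-free linear relation is interpolated", {
  x <- seq(0, 1, length.out = 20)
  y <- 2 * x + 1
  g <- fitGPR(x, y)
  iv <- predictInterval(g, x)
  expect_lt(max(abs(iv@mu - y)), 1e-4)
  expect_lt(mean(iv@sigma), 0.01)
})

test_that("fitting twice on the same data gives identical hyperparameters", {
  set.seed(30)
  x <- rnorm(40); y <- x + rnorm(40, 0, 0.2)
  g1 <- fitGPR(x, y); g2 <- fitGPR(x, y)
  expect_identical(g1@lengthScale, g2@lengthScale)
  expect_identical(g1@noiseVariance, g2@noiseVariance)
})

test_that("posterior mean and SD agree with a dense-matrix evaluation", {
  set.seed(31)
  x <- sort(runif(40, 0, 10))
  y <- sin(x) + rnorm(40, 0, 0.1)
  g <- fitGPR(x, y)
  xs <- seq(-1, 11, length.out = 25)
  iv <- predictInterval(g, xs)
  ref <- oracleGpPosterior(x, y, xs, g@lengthScale, g@signalVariance,
                           g@noiseVariance)
  expect_equal(iv@mu, ref$mu, tolerance = 1e-8)
  expect_equal(iv@sigma, ref$sigma, tolerance = 1e-8)
})

test_that("intervals are symmetric with width 2 z sigma", {
  set.seed(32)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.3)
  g <- fitGPR(x, y)
  iv <- predictInterval(g, c(-1, 0, 1))
  expect_equal(iv@upper - iv@mu, iv@mu - iv@lower, tolerance = 1e-12)
  expect_equal(iv@upper - iv@lower,
               2 * stats::qnorm(0.975) * iv@sigma, tolerance = 1e-12)
})

test_that("far from the data the width reverts to the prior", {
  set.seed(33)
  x <- runif(50); y <- x + rnorm(50, 0, 0.2)
  g <- fitGPR(x, y)
  iv <- predictInterval(g, 1e6)
  priorWidth <- 2 * stats::qnorm(0.975) *
    sqrt(g@signalVariance + g@noiseVariance)
  expect_equal(iv@upper - iv@lower, priorWidth, tolerance = 1e-6)
})

test_that("degenerate calibration floors the noise variance with a warning", {
  expect_warning(g <- fitGPR(rep(1, 5), rep(2, 5)), "degenerate")
  expect_gte(g@noiseVariance, 1e-12)
  iv <- predictInterval(g, 1)
  expect_lt(max(iv@upper - iv@lower), 1e-3)
})

test_that("prediction from an unfitted calibration is a state error", {
  empty <- new("GPRCalibration", fitted = FALSE)
  expect_error(predictInterval(empty, 1), "not been fitted")
})

test_that("too-few or misaligned calibration points are rejected", {
  expect_error(fitGPR(1:2, 1:2), "at least 3")
  expect_error(fitGPR(1:5, 1:4), "differ")
})

test_that("noise SD is recovered on a moderate simulation", {
  set.seed(34)
  n <- 400
  x <- runif(n, 0, 10)
  y <- x + rnorm(n, 0, 0.5)
  g <- fitGPR(x, y)
  expect_gt(sqrt(g@noiseVariance), 0.4)
  expect_lt(sqrt(g@noiseVariance), 0.6)
})
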