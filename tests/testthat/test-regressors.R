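test_that("deep enough trees fit a step function essentially exactly", {
  x <- matrix(seq(0, 1, length.out = 100), ncol = 1)
  y <- ifelse(x[, 1] > 0.5, 2, -1)
  m <- trainXGB(x, y, xgbConfig(nEstimators = 200, maxDepth = 3,
                                learningRate = 0.3))
  expect_lt(sqrt(mean((predictMoisture(m, x) - y)^2)), 1e-3)
})

test_that("zero learning rate leaves the constant base prediction", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20, 10)
  m <- trainXGB(x, y, xgbConfig(nEstimators = 1, learningRate = 0))
  pred <- predictMoisture(m, x)
  expect_lt(diff(range(pred)), 1e-10)
})

test_that("XGB training is deterministic for a fixed seed", {
  s <- smallSpectra(n = 40)
  x <- absorbance(s); y <- moisture(s)
  m1 <- trainXGB(x, y, xgbConfig(nEstimators = 30, seed = 3))
  m2 <- trainXGB(x, y, xgbConfig(nEstimators = 30, seed = 3))
  expect_identical(predictMoisture(m1, x), predictMoisture(m2, x))
})

test_that("channel-count mismatches name both counts", {
  x <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  m <- trainXGB(x, y, xgbConfig(nEstimators = 5))
  expect_error(predictMoisture(m, matrix(rnorm(40), 20, 2)),
               "2 channels.*trained with 3")
  x8 <- matrix(rnorm(160), 20, 8)
  mc <- trainCNN(x8, y, cnnConfig(epochs = 1, seed = 1))
  expect_error(predictMoisture(mc, matrix(rnorm(40), 20, 2)),
               "2 channels.*trained with 8")
})

test_that("degenerate training inputs are rejected up front", {
  expect_error(trainXGB(matrix(numeric(0), 0, 3), numeric(0)), "empty")
  expect_error(trainXGB(matrix(c(1, NaN, 1, 1), 2, 2), c(1, 2)), "NaN")
  expect_error(trainCNN(matrix(c(1, NaN, 1, 1), 2, 2), c(1, 2),
                        cnnConfig(epochs = 1)), "NaN")
})

test_that("a CNN converges to a constant predictor on constant targets", {
  set.seed(20)
  x <- matrix(rnorm(30 * 16), 30, 16)
  y <- rep(4.2, 30)
  m <- trainCNN(x, y, cnnConfig(epochs = 50, seed = 2))
  expect_lt(sqrt(mean((predictMoisture(m, x) - y)^2)), 1e-2)
})

test_that("network training is reproducible under a fixed seed", {
  set.seed(21)
  x <- matrix(rnorm(20 * 12), 20, 12)
  y <- rnorm(20, 10)
  p1 <- predictMoisture(trainCNN(x, y, cnnConfig(epochs = 3, seed = 7)), x)
  p2 <- predictMoisture(trainCNN(x, y, cnnConfig(epochs = 3, seed = 7)), x)
  expect_equal(p1, p2, tolerance = 1e-10)
  r1 <- predictMoisture(trainResNet(x, y, resnetConfig(epochs = 2, seed = 7)), x)
  r2 <- predictMoisture(trainResNet(x, y, resnetConfig(epochs = 2, seed = 7)), x)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("a residual block with zero conv weights is the identity", {
  blk <- nircal:::withLocalSeed(1, nircal:::newResBlock(4L, 4L, 1L))
  for (l in blk$main) {
    if (l$type == "conv") l$W[] <- 0
    if (l$type == "bnorm") l$beta[] <- 0
  }
  x <- array(abs(rnorm(2 * 10 * 4)), c(2, 10, 4))  # positive, so ReLU passes
  out <- nircal:::layerForward(blk, x, training = FALSE)
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("equal-width residual shortcuts add no parameters", {
  same <- nircal:::withLocalSeed(1, nircal:::newResBlock(8L, 8L, 1L))
  expect_false(same$project)
  proj <- nircal:::withLocalSeed(1, nircal:::newResBlock(8L, 16L, 2L))
  expect_true(proj$project)
})

test_that("too-short inputs for the pooling stack are a config error", {
  x <- matrix(rnorm(10 * 3), 10, 3)
  expect_error(trainCNN(x, rnorm(10), cnnConfig(epochs = 1)),
               "too short")
})

test_that("prediction sets stay aligned and labeled", {
  s <- smallSpectra(n = 20)
  x <- absorbance(s); y <- moisture(s)
  m <- trainXGB(x, y, xgbConfig(nEstimators = 300, maxDepth = 8,
                                learningRate = 0.3))
  p <- makePredictionSet(m, x, y, "train", "xgb", "full")
  expect_length(p@yPred, length(p@yActual))
  expect_identical(p@modelLabel, "xgb")
  # a tree ensemble driven to interpolation reproduces its training targets
  expect_lt(max(abs(p@yPred - p@yActual)), 0.05)
})
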