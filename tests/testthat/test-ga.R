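plantedData <- function(n = 80, p = 20, informative = c(3, 11),
                        noiseSd = 0.3, seed = 8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- rowSums(x[, informative, drop = FALSE]) + rnorm(n, 0, noiseSd)
  list(x = x, y = y)
}

test_that("a mask covering an exact linear signal scores near zero", {
  d <- plantedData(noiseSd = 0)
  cfg <- gaConfig(minSelected = 2, plsComponents = 2, seed = 1)
  mask <- seq_len(20) %in% c(3, 11)
  expect_gt(plsFitness(mask, d$x, d$y, cfg), -1e-8)
})

test_that("full-mask fitness equals an independent CV recomputation", {
  d <- plantedData()
  cfg <- gaConfig(seed = 5)
  folds <- nircal:::cvFolds(length(d$y), cfg$cvFolds, cfg$seed)
  expect_equal(plsFitness(rep(TRUE, 20), d$x, d$y, cfg, folds),
               -oracleCvMse(d$x, d$y, cfg$plsComponents, folds),
               tolerance = 1e-12)
})

test_that("pure-noise masks score strictly below informative masks", {
  d <- plantedData()
  cfg <- gaConfig(minSelected = 2, plsComponents = 2, seed = 2)
  good <- seq_len(20) %in% c(3, 11)
  bad <- seq_len(20) %in% c(5, 6)
  expect_gt(plsFitness(good, d$x, d$y, cfg),
            plsFitness(bad, d$x, d$y, cfg))
})

test_that("infeasible masks return -Inf instead of raising", {
  d <- plantedData()
  cfg <- gaConfig(minSelected = 5, seed = 1)
  expect_identical(plsFitness(seq_len(20) %in% 1:3, d$x, d$y, cfg), -Inf)
})

test_that("best fitness is non-decreasing under elitism and beats the full mask", {
  d <- plantedData()
  cfg <- gaConfig(populationSize = 24, nGenerations = 12, seed = 31)
  sel <- gaSelect(d$x, d$y, cfg)
  hist <- fitnessHistory(sel)
  expect_length(hist, 12)
  expect_true(all(diff(hist) >= 0))

  folds <- nircal:::cvFolds(length(d$y), cfg$cvFolds, cfg$seed)
  fullFit <- plsFitness(rep(TRUE, 20), d$x, d$y, cfg, folds)
  expect_gte(hist[length(hist)], fullFit)
})

test_that("selection is reproducible for a fixed seed", {
  d <- plantedData()
  cfg <- gaConfig(populationSize = 16, nGenerations = 6, seed = 99)
  a <- gaSelect(d$x, d$y, cfg)
  b <- gaSelect(d$x, d$y, cfg)
  expect_identical(selectedChannels(a), selectedChannels(b))
  expect_identical(fitnessHistory(a), fitnessHistory(b))
  expect_identical(channelImportance(a), channelImportance(b))
})

test_that("planted informative channels are recovered", {
  d <- plantedData(n = 100, p = 30, informative = c(7, 22), noiseSd = 0.3)
  cfg <- gaConfig(populationSize = 30, nGenerations = 15,
                  minSelected = 2, plsComponents = 4, seed = 12)
  sel <- gaSelect(d$x, d$y, cfg)
  expect_true(all(c(7, 22) %in% selectedChannels(sel)))
})

test_that("importance concentrates on the channel carrying the signal", {
  set.seed(10)
  x <- matrix(rnorm(200), 100, 2)
  y <- 2 * x[, 1]
  imp <- wavelengthImportance(x, y, 2)
  expect_gt(abs(imp[1]) / max(abs(imp[2]), 1e-12), 100)
})

test_that("importance of a constant response is identically zero", {
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(wavelengthImportance(x, rep(5, 20), 2), c(0, 0))
})

test_that("duplicated channels split importance but keep predictions", {
  set.seed(12)
  x <- matrix(rnorm(60), 30, 2)
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(30, 0, 0.05)
  fit1 <- plsFit(x, y, 2, scale = TRUE)
  xdup <- cbind(x, x[, 1])
  fit2 <- suppressWarnings(plsFit(xdup, y, 2, scale = TRUE))
  expect_equal(plsPredict(fit1, x), plsPredict(fit2, xdup),
               tolerance = 1e-6)
})

test_that("GA config invariants are enforced", {
  expect_error(gaConfig(crossoverRate = 1.2), "rates")
  expect_error(gaConfig(elitismCount = 100, populationSize = 100),
               "elitismCount")
  expect_error(gaConfig(minSelected = 0), "minSelected")
})
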