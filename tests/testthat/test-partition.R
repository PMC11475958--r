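test_that("three colinear points split to the two extremes", {
  sp <- spxySplit(matrix(c(0, 1, 2)), c(0, 1, 2), 2)
  expect_identical(trainIndices(sp), c(1L, 3L))
  expect_identical(testIndices(sp), 2L)

  ks <- ksSplit(matrix(c(0, 1, 2)), 2)
  expect_identical(trainIndices(ks), trainIndices(sp))
})

test_that("nTrain = n selects everything, leaving an empty test set", {
  x <- matrix(rnorm(12), 4)
  sp <- spxySplit(x, rnorm(4), 4)
  expect_identical(trainIndices(sp), 1:4)
  expect_length(testIndices(sp), 0)
})

test_that("identical spectra defer to the chemical distance", {
  x <- matrix(1, 3, 5)
  expect_warning(sp <- spxySplit(x, c(0, 5, 10), 2), "spectral")
  expect_identical(trainIndices(sp), c(1L, 3L))
})

test_that("all-identical rows fall back to the lowest-index tie-break", {
  x <- matrix(2, 4, 3)
  expect_warning(ks <- ksSplit(x, 2), "spectral")
  expect_identical(trainIndices(ks), c(1L, 2L))
})

test_that("selection matches the exhaustive max-min oracle on random data", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    p <- sample(1:4, 1)
    x <- matrix(round(rnorm(n * p), 2), n, p)
    y <- round(rnorm(n), 2)
    nTrain <- sample(2:(n - 1), 1)

    d <- oracleSpxyDist(x, y)
    expect_identical(trainIndices(spxySplit(x, y, nTrain)),
                     oracleMaxMin(d, nTrain))

    # constant y zeroes the chemical term, so the joint oracle reduces to KS
    suppressWarnings(
      expect_identical(trainIndices(ksSplit(x, nTrain)),
                       oracleMaxMin(oracleSpxyDist(x, rep(1, n)), nTrain)))
  }
})

test_that("splits are deterministic", {
  s <- smallSpectra(n = 25)
  a <- spxySplit(absorbance(s), moisture(s), 18)
  b <- spxySplit(absorbance(s), moisture(s), 18)
  expect_identical(trainIndices(a), trainIndices(b))
})

test_that("diagnostics report whether the test range is nested", {
  sp <- spxySplit(matrix(c(0, 1, 2, 3)), c(0, 1, 2, 3), 2)
  d <- splitDiagnostics(sp, c(0, 1, 2, 3))
  expect_true(d$testWithinTrainRange)
  expect_equal(unname(d$train["n"]), 2)
})

test_that("invalid split requests are rejected", {
  x <- matrix(rnorm(10), 5)
  expect_error(spxySplit(x, rnorm(5), 1), "nTrain")
  expect_error(spxySplit(x, rnorm(5), 6), "nTrain")
  expect_error(spxySplit(x, rnorm(4), 2), "differ")
})
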