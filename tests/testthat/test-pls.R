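test_that("PLS recovers an exact linear map with enough components", {
  set.seed(4)
  x <- matrix(rnorm(200), 40, 5)
  y <- 2 * x[, 1] - 3 * x[, 4] + 7
  fit <- plsFit(x, y, ncomp = 5)
  expect_lt(max(abs(plsPredict(fit, x) - y)), 1e-8)
})

test_that("full-component PLS equals ordinary least squares", {
  set.seed(5)
  x <- matrix(rnorm(300), 60, 5)
  y <- drop(x %*% c(1, -2, 0.5, 0, 3)) + rnorm(60, 0, 0.2)
  fit <- plsFit(x, y, ncomp = 5)
  ols <- stats::lm.fit(cbind(1, x), y)
  expect_equal(unname(fit$coefficients), unname(ols$coefficients[-1]),
               tolerance = 1e-8)
})

test_that("predictions match the mixOmics PLS1 implementation", {
  set.seed(6)
  x <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(NULL, paste0("ch", 1:8)))
  y <- drop(x %*% rnorm(8)) + rnorm(30, 0, 0.3)
  ours <- plsFit(x, y, ncomp = 3)
  ref <- mixOmics::pls(x, y, ncomp = 3, mode = "regression",
                       scale = FALSE)
  refPred <- predict(ref, x)$predict[, 1, 3]
  expect_equal(unname(plsPredict(ours, x)), unname(refPred),
               tolerance = 1e-6)
})

test_that("constant responses yield zero coefficients", {
  x <- matrix(rnorm(50), 10, 5)
  fit <- plsFit(x, rep(3, 10), ncomp = 2)
  expect_equal(fit$coefficients, numeric(5))
  expect_equal(plsPredict(fit, x), rep(3, 10))
})

test_that("rank-deficient requests are reduced with a warning", {
  x <- matrix(rnorm(30), 10, 3)
  x <- cbind(x, x[, 1])            # duplicated channel
  y <- x[, 2] + rnorm(10, 0, 0.1)
  expect_warning(fit <- plsFit(x, y, ncomp = 4), "reduced")
  expect_lte(fit$ncomp, 3)
})

test_that("channel-count mismatches at prediction are explicit", {
  fit <- plsFit(matrix(rnorm(40), 10, 4), rnorm(10), 2)
  expect_error(plsPredict(fit, matrix(rnorm(30), 10, 3)), "channels")
})
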