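ps <- function(a, p) PredictionSet(a, p)

interval <- function(lower, upper, mu = (lower + upper) / 2) {
  new("PredictionInterval", mu = mu, sigma = (upper - lower) / (2 * 1.96),
      lower = lower, upper = upper, confidence = 0.95)
}

test_that("R2 hits its anchor cases", {
  expect_equal(rSquared(ps(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(rSquared(ps(c(1, 2, 3), rep(2, 3))), 0)
  expect_equal(rSquared(ps(c(1, 2, 3), c(1, 2, 4))), 0.5)
  expect_error(rSquared(ps(c(2, 2, 2), c(1, 2, 3))), "variance")
})

test_that("RMSEP uses the n-1 divisor and scales linearly", {
  expect_equal(rmsep(ps(c(1, 2), c(1, 2))), 0)
  a <- c(0, 0, 0); r <- c(0.003, -0.005, 0.004)
  expect_equal(rmsep(ps(a, a - r)), 0.005)
  expect_equal(rmsep(ps(a, a - 2 * r)), 0.010)
})

test_that("RPD conventions behave as defined", {
  expect_equal(rpd(0.75), 2)
  expect_equal(rpd(0), 1)
  expect_identical(rpd(1), Inf)
  # SD convention: actual SD / RMSEP
  set.seed(40)
  a <- rnorm(50, 10, 1.24)
  p <- a + rnorm(50, 0, 0.1)
  expect_equal(rpdSD(ps(a, p)), stats::sd(a) / rmsep(ps(a, p)))
})

test_that("PICP counts strict containment only", {
  iv <- interval(lower = c(0, 0, 0, 0), upper = c(1, 1, 1, 1))
  expect_equal(picp(c(0.5, 0.2, 0.9, 0.4), iv), 1)
  expect_equal(picp(c(0.5, 0.2, 2, -1), iv), 0.5)
  # a value exactly on a bound is outside
  expect_equal(picp(c(1, 0, 0.5, 0.5), iv), 0.5)
  expect_error(picp(c(0.5), iv), "length")
})

test_that("PINAW normalizes mean width by the reference range", {
  y <- c(0, 4)
  expect_equal(pinaw(y, interval(c(0, 0), c(4, 4))), 1)
  expect_equal(pinaw(y, interval(c(1, 1), c(1, 1))), 0)
  expect_equal(pinaw(y, interval(c(0, 0), c(1, 3))), 0.5)
  expect_error(pinaw(c(2, 2), interval(c(0, 0), c(1, 1))), "range")
  # scale invariance under common rescaling
  k <- 7.3
  expect_equal(pinaw(k * c(0, 4), interval(k * c(0, 0), k * c(1, 3))), 0.5)
})

test_that("CWC is the coverage/width ratio", {
  expect_equal(cwc(1.000, 1.080), 0.926, tolerance = 5e-4)
  expect_equal(cwc(0.5, 0.5), 1)
  expect_equal(round(cwc(0.987, 0.241), 3), 4.095)
  expect_identical(cwc(0.9, 0), Inf)
})

test_that("percent-change conventions are computed as labeled", {
  expect_equal(relativeChange(0.582, 0.920, "increase_vs_old"), 58.1,
               tolerance = 0.05)
  expect_equal(relativeChange(0.019, 0.008, "reduction_vs_new"), 137.5,
               tolerance = 0.05)
  expect_equal(relativeChange(5, 5, "increase_vs_old"), 0)
  expect_equal(relativeChange(5, 5, "decrease_vs_old"), 0)
  expect_equal(relativeChange(5, 5, "reduction_vs_new"), 0)
  expect_error(relativeChange(0, 1, "increase_vs_old"), "denominator")
})

test_that("metric bundles return consistent one-row frames", {
  set.seed(41)
  a <- rnorm(30, 10, 2); p <- a + rnorm(30, 0, 0.4)
  pm <- pointMetrics(ps(a, p))
  expect_equal(pm$rpdEq, rpd(pm$r2))
  iv <- interval(p - 1, p + 1)
  im <- intervalMetrics(a, iv)
  expect_equal(im$cwc, im$picp / im$pinaw)
  expect_true(im$picp >= 0 && im$picp <= 1)
})
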