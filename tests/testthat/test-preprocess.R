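makeSet <- function(values, wl = seq(900, 1650, length.out = length(values))) {
  SpectraSet(matrix(values, nrow = 1), wl)
}

test_that("derivative of a constant spectrum is zero everywhere", {
  s <- makeSet(rep(0.7, 50))
  d <- sgFirstDerivative(s, sgParams(11, 2))
  expect_true(all(abs(absorbance(d)) < 1e-12))
})

test_that("derivative of a linear spectrum is its slope at every channel", {
  wl <- seq(900, 1650, length.out = 60)
  s <- makeSet(0.002 * wl, wl)
  d <- sgFirstDerivative(s, sgParams(11, 2))
  expect_equal(as.vector(absorbance(d)), rep(0.002, 60), tolerance = 1e-10)
})

test_that("cubic polynomials are differentiated exactly at interior points", {
  wl <- seq(900, 1650, length.out = 125)
  a <- c(1e-7, -2e-4, 0.15, -20)
  s <- makeSet(a[1] * wl^3 + a[2] * wl^2 + a[3] * wl + a[4], wl)
  truth <- 3 * a[1] * wl^2 + 2 * a[2] * wl + a[3]
  d <- sgFirstDerivative(s, sgParams(11, 3))
  interior <- 6:120
  expect_lt(max(abs(absorbance(d)[1, interior] - truth[interior])), 1e-10)
})

test_that("an additive offset leaves the derivative unchanged", {
  s <- smallSpectra(n = 4)
  d1 <- sgFirstDerivative(s)
  shifted <- SpectraSet(absorbance(s) + 0.37, wavelengths(s), moisture(s))
  d2 <- sgFirstDerivative(shifted)
  expect_equal(absorbance(d1), absorbance(d2), tolerance = 1e-10)
})

test_that("shape, moisture and finiteness are preserved", {
  s <- smallSpectra(n = 7)
  d <- sgFirstDerivative(s)
  expect_identical(dim(absorbance(d)), dim(absorbance(s)))
  expect_identical(moisture(d), moisture(s))
  expect_true(all(is.finite(absorbance(d))))
})

test_that("invalid grids and windows are rejected", {
  wl <- c(seq(900, 1000, by = 10), 1500)   # non-uniform
  s <- SpectraSet(matrix(rnorm(12), 1), wl)
  expect_error(sgFirstDerivative(s, sgParams(5, 2)), "not uniform")

  short <- makeSet(rnorm(9))
  expect_error(sgFirstDerivative(short, sgParams(11, 2)), "window")

  expect_error(sgParams(10, 2), "odd")
  expect_error(sgParams(3, 3), "greater than")
})
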