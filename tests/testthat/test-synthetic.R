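test_that("moisture draws respect truncation bounds and the target mean", {
  cfg <- generatorConfig(nSamples = 300, seed = 42)
  m <- generateMoisture(cfg)
  expect_length(m, 300)
  expect_true(all(m >= cfg$moistureMin & m <= cfg$moistureMax))

  # sample mean of a large draw sits within 3 SE of the nominal mean
  big <- generateMoisture(generatorConfig(nSamples = 5000, seed = 9))
  expect_lt(abs(mean(big) - 10.18), 3 * 2.78 / sqrt(5000))
})

test_that("zero-SD moisture collapses to a constant vector", {
  cfg <- generatorConfig(nSamples = 20, moistureSd = 0, seed = 1)
  expect_equal(generateMoisture(cfg), rep(10.18, 20))
})

test_that("invalid truncation bounds are a configuration error", {
  expect_error(generatorConfig(moistureMin = 15, moistureMax = 14.84),
               "truncation bounds")
  expect_error(generatorConfig(moistureMean = 2), "between")
})

test_that("generation is bit-identical for a fixed config and seed", {
  cfg <- generatorConfig(nSamples = 25, seed = 77)
  s1 <- simulateSpectra(cfg)
  s2 <- simulateSpectra(cfg)
  expect_identical(absorbance(s1), absorbance(s2))
  expect_identical(moisture(s1), moisture(s2))
})

test_that("no absorbers means all-zero spectra", {
  cfg <- generatorConfig(
    nSamples = 3, seed = 1,
    bands = list(absorptionBand(1430, 45, 0, moistureCoupling = 0)),
    scatterSlopeSd = 0, scatterOffsetSd = 0, noiseSd = 0)
  s <- generateSpectra(c(0, 0, 0), cfg)
  expect_true(all(absorbance(s) == 0))
})

test_that("the water band dominates at the channel nearest 1430 nm", {
  cfg <- generatorConfig(nSamples = 5, seed = 2,
                         bands = defaultBands()[c("water", "carbohydrate")],
                         scatterSlopeSd = 0, scatterOffsetSd = 0,
                         noiseSd = 0)
  s <- simulateSpectra(cfg)
  target <- which.min(abs(wavelengths(s) - 1430))
  expect_true(all(apply(absorbance(s), 1, which.max) == target))
})

test_that("absorbance at the water band is monotone in moisture", {
  cfg <- generatorConfig(nSamples = 2, seed = 3, scatterSlopeSd = 0,
                         scatterOffsetSd = 0, noiseSd = 0)
  s <- generateSpectra(c(5, 15), cfg)
  ch <- which.min(abs(wavelengths(s) - 1430))
  expect_gt(absorbance(s)[2, ch], absorbance(s)[1, ch])

  # property: strictly increasing across a moisture ladder
  ladder <- generateSpectra(seq(2, 20, by = 2), cfg)
  expect_true(all(diff(absorbance(ladder)[, ch]) > 0))
})

test_that("moisture outside [0, 100] is rejected", {
  cfg <- generatorConfig(nSamples = 2, seed = 1)
  expect_error(generateSpectra(c(-1, 5), cfg), "0, 100")
})

test_that("CSV round trip preserves values, wavelengths and moisture", {
  s <- smallSpectra(n = 3, nChannels = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(s, path)
  r <- readSpectra(path)
  expect_equal(absorbance(r), absorbance(s), tolerance = 1e-12)
  expect_equal(wavelengths(r), wavelengths(s), tolerance = 1e-12)
  expect_equal(moisture(r), moisture(s), tolerance = 1e-12)
})

test_that("malformed CSVs raise parse errors naming the problem cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("900,1000,1100", "0.1,0.2,0.3", "0.1,,0.3"), path)
  expect_error(readSpectra(path), "row 2, column '1000'")

  writeLines(c("900,1000,1100", "0.1,0.2,0.3", "0.1,0.2"), path)
  expect_error(readSpectra(path), "ragged")

  writeLines(c("900,1100,1000", "0.1,0.2,0.3"), path)
  expect_error(readSpectra(path), "not strictly increasing")

  writeLines(c("900,abc,1100", "0.1,0.2,0.3"), path)
  expect_error(readSpectra(path), "non-numeric wavelength")
})

test_that("SpectraSet validity rejects inconsistent objects", {
  expect_error(SpectraSet(matrix(1, 2, 3), c(900, 1000)), "columns")
  expect_error(SpectraSet(matrix(1, 2, 2), c(1000, 900)), "increasing")
  expect_error(SpectraSet(matrix(1, 2, 2), c(900, 1000), moisture = 1),
               "length")
  expect_error(SpectraSet(matrix(c(1, NA, 1, 1), 2, 2), c(900, 1000)),
               "non-finite")
})
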