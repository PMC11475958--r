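# Seeded synthetic NIR spectra with moisture-dependent absorption structure.
# Spectra are sums of Gaussian absorption bands whose amplitudes may couple
# linearly to moisture (mass fraction), degraded by per-sample multiplicative
# and additive scatter and i.i.d. channel noise.

#' Describe one Gaussian absorption band
#'
#' Band amplitude for sample i is
#' `baseAmplitude + moistureCoupling * (moisture_i / 100)` (moisture enters
#' as a mass fraction); the band shape is Gaussian in wavelength.
#'
#' @param centerNm band center in nm.
#' @param widthNm Gaussian SD in nm; must be > 0.
#' @param baseAmplitude moisture-independent absorbance amplitude; >= 0.
#' @param moistureCoupling absorbance per unit moisture mass fraction
#'   (0 for moisture-independent bands).
#' @return a validated list of class "AbsorptionBand".
#' @export
absorptionBand <- function(centerNm, widthNm, baseAmplitude,
                           moistureCoupling = 0) {
  stopifnot(widthNm > 0, baseAmplitude >= 0)
  structure(list(centerNm = centerNm, widthNm = widthNm,
                 baseAmplitude = baseAmplitude,
                 moistureCoupling = moistureCoupling),
            class = "AbsorptionBand")
}

#' Default absorption bands for dried-laver NIR spectra
#'
#' Encodes the spectral features of dried Porphyra yezoensis in the
#' 900-1650 nm window: the O-H stretching first overtone of water near
#' 1430 nm (strongly moisture-coupled), the C-H stretching second overtone
#' of carbohydrates near 1180 nm, a polysaccharide-water interaction band
#' near 1375 nm (weakly moisture-coupled), and a broad baseline hump.
#'
#' @return list of [absorptionBand()] objects.
#' @export
defaultBands <- function() {
  list(
    water          = absorptionBand(1430, 45, 0.08, moistureCoupling = 3.0),
    carbohydrate   = absorptionBand(1180, 35, 0.18, moistureCoupling = 0),
    polysaccharide = absorptionBand(1375, 28, 0.03, moistureCoupling = 0.8),
    baseline       = absorptionBand(1250, 300, 0.25, moistureCoupling = 0)
  )
}

#' Configure the synthetic spectra generator
#'
#' Defaults emulate the acquisition setup of a handheld NIR spectrometer in
#' the 900-1650 nm range digitized to 125 channels, and a moisture
#' distribution with mean 10.18%, SD 2.78%, truncated to [4.37, 14.84]%.
#'
#' @param nSamples number of samples to generate.
#' @param lambdaStartNm,lambdaEndNm wavelength bounds in nm.
#' @param nChannels number of evenly spaced wavelength channels (>= 2).
#' @param moistureMean,moistureSd,moistureMin,moistureMax moisture
#'   distribution parameters in percent mass fraction; values are drawn
#'   from a truncated normal.
#' @param bands list of [absorptionBand()] objects.
#' @param scatterSlopeSd SD of the per-sample multiplicative scatter factor
#'   (spectrum scaled by 1 + a_i).
#' @param scatterOffsetSd SD of the per-sample additive offset (absorbance).
#' @param noiseSd SD of i.i.d. Gaussian channel noise (absorbance).
#' @param seed integer seed; drives moisture, scatter and noise through
#'   independent substreams so each can be regenerated in isolation.
#' @return a validated list of class "GeneratorConfig".
#' @export
generatorConfig <- function(nSamples = 380,
                            lambdaStartNm = 900, lambdaEndNm = 1650,
                            nChannels = 125,
                            moistureMean = 10.18, moistureSd = 2.78,
                            moistureMin = 4.37, moistureMax = 14.84,
                            bands = defaultBands(),
                            scatterSlopeSd = 0.05,
                            scatterOffsetSd = 0.02,
                            noiseSd = 0.001,
                            seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples),
              lambdaStartNm = lambdaStartNm, lambdaEndNm = lambdaEndNm,
              nChannels = as.integer(nChannels),
              moistureMean = moistureMean, moistureSd = moistureSd,
              moistureMin = moistureMin, moistureMax = moistureMax,
              bands = bands,
              scatterSlopeSd = scatterSlopeSd,
              scatterOffsetSd = scatterOffsetSd,
              noiseSd = noiseSd, seed = as.integer(seed))
  if (cfg$lambdaStartNm >= cfg$lambdaEndNm)
    stop("lambdaStartNm must be < lambdaEndNm")
  if (cfg$nChannels < 2L) stop("nChannels must be >= 2")
  if (cfg$moistureMin >= cfg$moistureMax)
    stop("invalid truncation bounds: moistureMin must be < moistureMax")
  if (!(cfg$moistureMin < cfg$moistureMean &&
        cfg$moistureMean < cfg$moistureMax))
    stop("moistureMean must lie strictly between moistureMin and moistureMax")
  if (cfg$moistureSd < 0 || cfg$scatterSlopeSd < 0 ||
      cfg$scatterOffsetSd < 0 || cfg$noiseSd < 0)
    stop("all SDs must be >= 0")
  for (b in cfg$bands)
    if (!inherits(b, "AbsorptionBand")) stop("bands must be AbsorptionBand objects")
  structure(cfg, class = "GeneratorConfig")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Draw a truncated-normal moisture vector
#'
#' Samples `nSamples` moisture values (percent) from
#' N(moistureMean, moistureSd^2) truncated to [moistureMin, moistureMax]
#' by rejection; reproducible for a fixed seed.
#'
#' @param config a [generatorConfig()].
#' @return numeric vector of length `nSamples`, all inside the bounds.
#' @examples
#' m <- generateMoisture(generatorConfig(nSamples = 10, seed = 7))
#' range(m)
#' @export
generateMoisture <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  n <- config$nSamples
  if (config$moistureSd == 0) return(rep(config$moistureMean, n))
  withLocalSeed(config$seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n, config$moistureMean, config$moistureSd)
      out <- c(out, draw[draw >= config$moistureMin &
                         draw <= config$moistureMax])
    }
    out[seq_len(n)]
  })
}

#' Generate synthetic absorbance spectra for given moisture values
#'
#' Clean spectra are sums over the configured bands of
#' `[baseAmplitude + moistureCoupling * (moisture_i/100)] *
#'  exp(-(lambda - center)^2 / (2 width^2))`;
#' each sample is then scaled by (1 + a_i), offset by b_i
#' (a_i, b_i per-sample Gaussian scatter terms) and perturbed by i.i.d.
#' Gaussian channel noise.
#'
#' @param moistureValues numeric vector of moisture contents in percent,
#'   each in [0, 100].
#' @param config a [generatorConfig()]; `nSamples` is taken from the length
#'   of `moistureValues`.
#' @return a [SpectraSet-class] with the moisture vector attached.
#' @export
generateSpectra <- function(moistureValues, config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (any(moistureValues < 0 | moistureValues > 100))
    stop("moisture values must lie in [0, 100] percent")
  n <- length(moistureValues)
  wl <- seq(config$lambdaStartNm, config$lambdaEndNm,
            length.out = config$nChannels)
  clean <- matrix(0, n, config$nChannels)
  frac <- moistureValues / 100
  for (b in config$bands) {
    shape <- exp(-(wl - b$centerNm)^2 / (2 * b$widthNm^2))
    amp <- b$baseAmplitude + b$moistureCoupling * frac
    clean <- clean + outer(amp, shape)
  }
  # scatter and noise substreams are independent of the moisture stream
  a <- withLocalSeed(config$seed + 1L,
                     stats::rnorm(n, 0, config$scatterSlopeSd))
  bOff <- withLocalSeed(config$seed + 2L,
                        stats::rnorm(n, 0, config$scatterOffsetSd))
  noise <- withLocalSeed(config$seed + 3L,
                         matrix(stats::rnorm(n * config$nChannels, 0,
                                             config$noiseSd),
                                n, config$nChannels))
  ab <- clean * (1 + a) + bOff + noise
  SpectraSet(ab, wl, moistureValues)
}

#' Generate a complete synthetic SpectraSet
#'
#' Convenience wrapper: draws moisture with [generateMoisture()] and
#' spectra with [generateSpectra()] from one config.
#'
#' @param config a [generatorConfig()].
#' @return a [SpectraSet-class].
#' @examples
#' s <- simulateSpectra(generatorConfig(nSamples = 20, seed = 3))
#' s
#' @export
simulateSpectra <- function(config = generatorConfig()) {
  generateSpectra(generateMoisture(config), config)
}

#' Write a SpectraSet to CSV
#'
#' One row per sample; the header row carries the wavelengths in nm and,
#' when moisture is attached, a final column "moisture_percent".
#'
#' @param set a [SpectraSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(set, path) {
  stopifnot(is(set, "SpectraSet"))
  df <- as.data.frame(absorbance(set))
  names(df) <- format(wavelengths(set), trim = TRUE, digits = 10)
  if (!is.null(moisture(set))) df$moisture_percent <- moisture(set)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a SpectraSet from CSV
#'
#' Inverse of [writeSpectra()]: the header row must hold numeric
#' wavelengths (strictly increasing) and may end with a
#' "moisture_percent" column. Malformed files (ragged rows, non-numeric
#' or missing cells, unsorted wavelengths) raise parse errors naming the
#' offending row/column.
#'
#' @param path CSV file path.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(fields)) > 1L)
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                 which(fields != fields[1])[1],
                 fields[which(fields != fields[1])[1]], fields[1]))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  cols <- names(df)
  hasMoisture <- length(cols) && cols[length(cols)] == "moisture_percent"
  wlCols <- if (hasMoisture) cols[-length(cols)] else cols
  wl <- suppressWarnings(as.numeric(wlCols))
  if (anyNA(wl))
    stop("non-numeric wavelength in header: column ",
         which(is.na(wl))[1], " ('", wlCols[which(is.na(wl))[1]], "')")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("wavelengths in header are not strictly increasing (column ",
         which(diff(wl) <= 0)[1] + 1L, ")")
  num <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1,
                                    dimnames = list(NULL, names(df)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                 bad[1], cols[bad[2]]))
  }
  ab <- num[, seq_along(wl), drop = FALSE]
  dimnames(ab) <- NULL
  m <- if (hasMoisture) num[, length(cols)] else NULL
  SpectraSet(ab, wl, m)
}
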