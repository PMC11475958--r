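#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib nircal, .registration = TRUE
NULL

#' SpectraSet: absorbance spectra with a wavelength grid
#'
#' The universal payload between pipeline stages: an absorbance matrix
#' (samples x channels), the wavelength grid in nm, and an optional
#' moisture vector in percent mass fraction.
#'
#' @slot wavelengths numeric vector of wavelengths in nm, strictly increasing.
#' @slot absorbance numeric matrix, one row per sample, one column per
#'   wavelength channel.
#' @slot moisture numeric vector of moisture contents in percent; length 0
#'   when no reference values are attached.
#'
#' @seealso [SpectraSet()] for the user-facing constructor,
#'   [generateSpectra()], [readSpectra()].
#' @exportClass SpectraSet
setClass("SpectraSet",
  representation(
    wavelengths = "numeric",
    absorbance  = "matrix",
    moisture    = "numeric"
  ),
  prototype(
    wavelengths = numeric(0),
    absorbance  = matrix(numeric(0), 0, 0),
    moisture    = numeric(0)
  )
)

setValidity("SpectraSet", function(object) {
  msg <- character(0)
  wl <- object@wavelengths
  ab <- object@absorbance
  if (ncol(ab) != length(wl))
    msg <- c(msg, sprintf("absorbance has %d columns but %d wavelengths",
                          ncol(ab), length(wl)))
  if (length(wl) > 1 && any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(ab) && !all(is.finite(ab)))
    msg <- c(msg, "absorbance contains non-finite values")
  if (length(wl) && !all(is.finite(wl)))
    msg <- c(msg, "wavelengths contain non-finite values")
  m <- object@moisture
  if (length(m) && length(m) != nrow(ab))
    msg <- c(msg, sprintf("moisture has length %d but there are %d samples",
                          length(m), nrow(ab)))
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "moisture contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, samples x channels.
#' @param wavelengths numeric vector of channel wavelengths in nm,
#'   strictly increasing, length `ncol(absorbance)`.
#' @param moisture optional numeric vector of moisture contents (percent),
#'   one per sample.
#'
#' @return A [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(runif(15), 3, 5), seq(900, 1650, length.out = 5))
#' nSamples(s)
#' @export
SpectraSet <- function(absorbance, wavelengths, moisture = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  new("SpectraSet",
      wavelengths = as.numeric(wavelengths),
      absorbance  = absorbance,
      moisture    = if (is.null(moisture)) numeric(0) else as.numeric(moisture))
}

#' SplitResult: a train/test partition of a sample set
#'
#' @slot trainIndices,testIndices integer vectors of 1-based sample indices;
#'   disjoint, jointly covering all samples.
#' @slot method partitioning algorithm label ("spxy" or "ks").
#' @slot nTrain requested training-set size.
#' @exportClass SplitResult
setClass("SplitResult",
  representation(
    trainIndices = "integer",
    testIndices  = "integer",
    method       = "character",
    nTrain       = "integer"
  )
)

setValidity("SplitResult", function(object) {
  msg <- character(0)
  tr <- object@trainIndices; te <- object@testIndices
  if (anyDuplicated(c(tr, te)))
    msg <- c(msg, "train and test indices overlap or contain duplicates")
  n <- length(tr) + length(te)
  if (n && !setequal(c(tr, te), seq_len(n)))
    msg <- c(msg, "indices must jointly cover 1..n")
  if (length(tr) != object@nTrain)
    msg <- c(msg, sprintf("train set has %d indices, nTrain is %d",
                          length(tr), object@nTrain))
  if (!object@method %in% c("spxy", "ks"))
    msg <- c(msg, "method must be 'spxy' or 'ks'")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: GA-selected wavelength channels
#'
#' @slot selectedChannels sorted integer channel indices into the grid.
#' @slot selectedWavelengths corresponding wavelengths in nm.
#' @slot fitnessHistory best fitness (negative CV-MSE) per generation.
#' @slot importance standardized PLS regression coefficient per selected
#'   channel, for interpreting which wavelengths drive the prediction.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    selectedChannels    = "integer",
    selectedWavelengths = "numeric",
    fitnessHistory      = "numeric",
    importance          = "numeric"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  ch <- object@selectedChannels
  if (anyDuplicated(ch)) msg <- c(msg, "selected channels must be unique")
  if (is.unsorted(ch)) msg <- c(msg, "selected channels must be sorted")
  if (length(ch) != length(object@selectedWavelengths))
    msg <- c(msg, "channels and wavelengths differ in length")
  if (length(ch) != length(object@importance))
    msg <- c(msg, "importance must align with selected channels")
  if (length(msg)) msg else TRUE
})

#' PredictionSet: aligned actual and predicted moisture values
#'
#' @slot yActual,yPred aligned numeric vectors on the modeling scale.
#' @slot setLabel "train" or "test".
#' @slot modelLabel model family label (e.g. "xgb", "cnn", "resnet").
#' @slot wavelengthSetLabel "full" or "selected".
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(
    yActual            = "numeric",
    yPred              = "numeric",
    setLabel           = "character",
    modelLabel         = "character",
    wavelengthSetLabel = "character"
  )
)

setValidity("PredictionSet", function(object) {
  msg <- character(0)
  if (length(object@yActual) != length(object@yPred))
    msg <- c(msg, sprintf("yActual (%d) and yPred (%d) differ in length",
                          length(object@yActual), length(object@yPred)))
  if (!all(is.finite(object@yActual)) || !all(is.finite(object@yPred)))
    msg <- c(msg, "predictions must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionSet
#'
#' @param yActual,yPred aligned numeric vectors.
#' @param setLabel "train" or "test".
#' @param modelLabel model family label.
#' @param wavelengthSetLabel "full" or "selected".
#' @return A [PredictionSet-class] object.
#' @export
PredictionSet <- function(yActual, yPred, setLabel = "test",
                          modelLabel = "model", wavelengthSetLabel = "full") {
  new("PredictionSet", yActual = as.numeric(yActual),
      yPred = as.numeric(yPred), setLabel = setLabel,
      modelLabel = modelLabel, wavelengthSetLabel = wavelengthSetLabel)
}

#' PredictionInterval: per-sample Gaussian-process prediction bounds
#'
#' Bounds are `mu +/- z * sigma` where `z` is the two-sided normal quantile
#' of the confidence level and `sigma` is the predictive standard deviation
#' (including observation noise).
#'
#' @slot mu posterior predictive mean per sample.
#' @slot sigma posterior predictive standard deviation per sample.
#' @slot lower,upper interval bounds per sample.
#' @slot confidence nominal coverage level (default 0.95).
#' @exportClass PredictionInterval
setClass("PredictionInterval",
  representation(
    mu         = "numeric",
    sigma      = "numeric",
    lower      = "numeric",
    upper      = "numeric",
    confidence = "numeric"
  )
)

setValidity("PredictionInterval", function(object) {
  msg <- character(0)
  n <- length(object@mu)
  if (length(object@sigma) != n || length(object@lower) != n ||
      length(object@upper) != n)
    msg <- c(msg, "mu, sigma, lower, upper must have equal lengths")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be non-negative")
  if (any(object@lower > object@mu + 1e-12) ||
      any(object@upper < object@mu - 1e-12))
    msg <- c(msg, "bounds must bracket mu")
  if (object@confidence <= 0 || object@confidence >= 1)
    msg <- c(msg, "confidence must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' GPRCalibration: a fitted Gaussian-process calibration
#'
#' Maps model predictions to reference values with a Matern 5/2 GP;
#' stores optimized hyperparameters and the posterior state needed
#' for interval prediction.
#'
#' @slot lengthScale,signalVariance Matern 5/2 kernel hyperparameters.
#' @slot noiseVariance Gaussian observation-noise variance.
#' @slot xTrain,yTrain calibration inputs/targets.
#' @slot meanY constant prior mean (mean of calibration targets).
#' @slot L lower Cholesky factor of K + noiseVariance * I.
#' @slot alpha precomputed solve of (K + noiseVariance * I) against
#'   centered targets.
#' @slot fitted whether the posterior state is populated.
#' @exportClass GPRCalibration
setClass("GPRCalibration",
  representation(
    lengthScale    = "numeric",
    signalVariance = "numeric",
    noiseVariance  = "numeric",
    xTrain         = "numeric",
    yTrain         = "numeric",
    meanY          = "numeric",
    L              = "matrix",
    alpha          = "numeric",
    fitted         = "logical"
  ),
  prototype(fitted = FALSE)
)

setValidity("GPRCalibration", function(object) {
  msg <- character(0)
  if (length(object@noiseVariance) && object@noiseVariance < 0)
    msg <- c(msg, "noiseVariance must be >= 0")
  if (length(msg)) msg else TRUE
})
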