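#' Accessors for SpectraSet objects
#'
#' @param x a [SpectraSet-class].
#' @param value replacement moisture vector (percent) or NULL to drop.
#' @return `wavelengths()` the grid in nm; `absorbance()` the samples x
#'   channels matrix; `moisture()` the moisture vector in percent (NULL when
#'   absent); `nSamples()`/`nChannels()` the dimensions.
#' @name SpectraSet-accessors
NULL

#' @rdname SpectraSet-accessors
setMethod("wavelengths", "SpectraSet", function(x) x@wavelengths)

#' @rdname SpectraSet-accessors
setMethod("absorbance", "SpectraSet", function(x) x@absorbance)

#' @rdname SpectraSet-accessors
setMethod("moisture", "SpectraSet", function(x)
  if (length(x@moisture)) x@moisture else NULL)

#' @rdname SpectraSet-accessors
setMethod("moisture<-", "SpectraSet", function(x, value) {
  x@moisture <- if (is.null(value)) numeric(0) else as.numeric(value)
  validObject(x)
  x
})

#' @rdname SpectraSet-accessors
setMethod("nSamples", "SpectraSet", function(x) nrow(x@absorbance))

#' @rdname SpectraSet-accessors
setMethod("nChannels", "SpectraSet", function(x) ncol(x@absorbance))

setMethod("show", "SpectraSet", function(object) {
  wl <- object@wavelengths
  cat(sprintf("SpectraSet: %d samples x %d channels\n",
              nrow(object@absorbance), ncol(object@absorbance)))
  if (length(wl))
    cat(sprintf("  wavelengths: %.1f .. %.1f nm\n", wl[1], wl[length(wl)]))
  if (length(object@moisture))
    cat(sprintf("  moisture: mean %.2f%%, range [%.2f, %.2f]\n",
                mean(object@moisture), min(object@moisture),
                max(object@moisture)))
  else cat("  moisture: absent\n")
})

#' Accessors for SplitResult objects
#'
#' @param x a [SplitResult-class].
#' @return integer index vectors.
#' @name SplitResult-accessors
NULL

#' @rdname SplitResult-accessors
setMethod("trainIndices", "SplitResult", function(x) x@trainIndices)

#' @rdname SplitResult-accessors
setMethod("testIndices", "SplitResult", function(x) x@testIndices)

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult (%s): %d train / %d test\n", object@method,
              length(object@trainIndices), length(object@testIndices)))
})

#' Accessors for SelectionResult objects
#'
#' @param x a [SelectionResult-class].
#' @return `selectedChannels()` sorted channel indices;
#'   `selectedWavelengths()` the wavelengths in nm; `fitnessHistory()` best
#'   fitness per generation; `channelImportance()` standardized PLS
#'   coefficients aligned with the selected channels.
#' @name SelectionResult-accessors
NULL

#' @rdname SelectionResult-accessors
setMethod("selectedChannels", "SelectionResult", function(x)
  x@selectedChannels)

#' @rdname SelectionResult-accessors
setMethod("selectedWavelengths", "SelectionResult", function(x)
  x@selectedWavelengths)

#' @rdname SelectionResult-accessors
setMethod("fitnessHistory", "SelectionResult", function(x) x@fitnessHistory)

#' @rdname SelectionResult-accessors
setMethod("channelImportance", "SelectionResult", function(x) x@importance)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d channels selected over %d generations\n",
              length(object@selectedChannels), length(object@fitnessHistory)))
  if (length(object@fitnessHistory))
    cat(sprintf("  best fitness: %.6g\n",
                object@fitnessHistory[length(object@fitnessHistory)]))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet [%s / %s / %s]: n = %d\n", object@modelLabel,
              object@wavelengthSetLabel, object@setLabel,
              length(object@yActual)))
})

setMethod("show", "PredictionInterval", function(object) {
  cat(sprintf("PredictionInterval: n = %d, confidence = %.2f\n",
              length(object@mu), object@confidence))
  if (length(object@sigma))
    cat(sprintf("  mean width: %.4g\n", mean(object@upper - object@lower)))
})

setMethod("show", "GPRCalibration", function(object) {
  if (!object@fitted) {
    cat("GPRCalibration: unfitted\n")
  } else {
    cat(sprintf(paste0("GPRCalibration (Matern 5/2): n = %d\n",
                       "  length-scale %.4g, signal var %.4g, ",
                       "noise var %.4g\n"),
                length(object@xTrain), object@lengthScale,
                object@signalVariance, object@noiseVariance))
  }
})
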