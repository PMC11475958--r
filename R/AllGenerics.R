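#' @rdname SpectraSet-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("moisture", function(x) standardGeneric("moisture"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("moisture<-", function(x, value) standardGeneric("moisture<-"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname SplitResult-accessors
#' @export
setGeneric("trainIndices", function(x) standardGeneric("trainIndices"))

#' @rdname SplitResult-accessors
#' @export
setGeneric("testIndices", function(x) standardGeneric("testIndices"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("selectedChannels", function(x) standardGeneric("selectedChannels"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("selectedWavelengths",
           function(x) standardGeneric("selectedWavelengths"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("fitnessHistory", function(x) standardGeneric("fitnessHistory"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("channelImportance", function(x) standardGeneric("channelImportance"))

#' Predict moisture from a fitted regressor
#'
#' @param object a fitted model handle from [trainXGB()], [trainCNN()] or
#'   [trainResNet()].
#' @param x numeric matrix of spectra (samples x channels) with the same
#'   channel count as the training matrix.
#' @return numeric vector of predictions on the training response scale.
#' @export
setGeneric("predictMoisture",
           function(object, x) standardGeneric("predictMoisture"))
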