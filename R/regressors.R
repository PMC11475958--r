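# The three regressor families of the comparison: gradient-boosted trees
# (XGBoost), a three-layer 1-D CNN, and a 1-D ResNet-18. All accept any
# channel count (full grid or a GA-selected subset) and produce aligned
# PredictionSet objects for the metric and uncertainty stages.

#' Configure the gradient-boosted tree regressor
#'
#' Trees are fitted to the squared-error objective with the regularized
#' complexity penalty `gamma * T + lambda/2 * ||w||^2` over leaf count T
#' and leaf weights w; `regLambda` and `gamma` pass those penalty weights
#' through to the boosting implementation.
#'
#' @param nEstimators boosting rounds.
#' @param maxDepth maximum tree depth.
#' @param learningRate shrinkage step size (> 0 in normal use).
#' @param regLambda L2 leaf-weight penalty (>= 0).
#' @param gamma per-leaf complexity penalty (>= 0).
#' @param seed integer seed (single-thread training is deterministic).
#' @return a validated list of class "XGBConfig".
#' @export
xgbConfig <- function(nEstimators = 400L, maxDepth = 6L,
                      learningRate = 0.05, regLambda = 1, gamma = 0,
                      seed = 1L) {
  if (regLambda < 0 || gamma < 0) stop("penalties must be >= 0")
  if (learningRate < 0) stop("learningRate must be >= 0")
  structure(list(nEstimators = as.integer(nEstimators),
                 maxDepth = as.integer(maxDepth),
                 learningRate = learningRate, regLambda = regLambda,
                 gamma = gamma, seed = as.integer(seed)),
            class = "XGBConfig")
}

#' Configure the 1-D CNN regressor
#'
#' Architecture: conv(64) -> max pool -> conv(128) -> max pool ->
#' conv(256) -> flatten -> dense -> dense(1), ReLU activations, trained
#' by Adam on mean squared error for exactly `epochs` epochs (the epoch
#' count, not a loss threshold, ends training).
#'
#' @param convChannels kernels per convolutional layer.
#' @param stemKernel,kernelSize kernel sizes of the first and the
#'   remaining convolutions (channels).
#' @param denseUnits units of the hidden dense layer.
#' @param learningRate Adam learning rate.
#' @param epochs training epochs (>= 1).
#' @param batchSize mini-batch size.
#' @param seed integer seed for init and shuffling.
#' @return a validated list of class "CNNConfig".
#' @export
cnnConfig <- function(convChannels = c(64L, 128L, 256L), stemKernel = 7L,
                      kernelSize = 3L, denseUnits = 64L,
                      learningRate = 0.001, epochs = 800L,
                      batchSize = 32L, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (length(convChannels) != 3L) stop("three convolutional layers expected")
  structure(list(convChannels = as.integer(convChannels),
                 stemKernel = as.integer(stemKernel),
                 kernelSize = as.integer(kernelSize),
                 denseUnits = as.integer(denseUnits),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "CNNConfig")
}

#' Configure the 1-D ResNet-18 regressor
#'
#' Architecture: stem convolution (stride 2) + max pool, four residual
#' stages of two basic blocks each (16 convolutions within the blocks),
#' batch normalization inside blocks, identity shortcuts (a 1x1
#' projection only where width or resolution changes), global average
#' pool and a linear head. Trained by Adam on mean squared error for
#' exactly `epochs` epochs.
#'
#' @param widths channel widths of the four residual stages; the default
#'   quarters the image-classification widths (32/64/128/256), the 1-D
#'   adaptation for short spectral inputs, and is fully configurable.
#' @param stemKernel stem convolution kernel size.
#' @param learningRate Adam learning rate.
#' @param epochs training epochs (>= 1).
#' @param batchSize mini-batch size.
#' @param seed integer seed for init and shuffling.
#' @return a validated list of class "ResNetConfig".
#' @export
resnetConfig <- function(widths = c(32L, 64L, 128L, 256L), stemKernel = 7L,
                         learningRate = 0.0001, epochs = 1200L,
                         batchSize = 32L, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (length(widths) != 4L) stop("four residual stages expected")
  structure(list(widths = as.integer(widths),
                 stemKernel = as.integer(stemKernel),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "ResNetConfig")
}

checkTrainingData <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set")
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  if (anyNA(x) || any(!is.finite(x))) stop("features contain NaN/non-finite values")
  if (anyNA(y) || any(!is.finite(y))) stop("targets contain NaN/non-finite values")
  x
}

#' Train the gradient-boosted tree regressor
#'
#' @param x training spectra (samples x channels), full or selected.
#' @param y aligned response vector (moisture, model scale).
#' @param config an [xgbConfig()].
#' @return a fitted model handle for [predictMoisture()].
#' @export
trainXGB <- function(x, y, config = xgbConfig()) {
  stopifnot(inherits(config, "XGBConfig"))
  x <- checkTrainingData(x, y)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1)
  params <- list(objective = "reg:squarederror",
                 max_depth = config$maxDepth,
                 eta = config$learningRate,
                 lambda = config$regLambda,
                 gamma = config$gamma,
                 nthread = 1,
                 seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$nEstimators, verbose = 0)
  structure(list(booster = booster, nChannels = ncol(x), config = config),
            class = c("nircalXGB", "nircalModel"))
}

#' Train the 1-D CNN regressor
#'
#' @inheritParams trainXGB
#' @param config a [cnnConfig()].
#' @return a fitted model handle for [predictMoisture()].
#' @export
trainCNN <- function(x, y, config = cnnConfig()) {
  stopifnot(inherits(config, "CNNConfig"))
  x <- checkTrainingData(x, y)
  net <- trainNetwork(x, y,
                      build = function(len)
                        buildCnn1d(len, config$convChannels,
                                   config$denseUnits, config$stemKernel,
                                   config$kernelSize),
                      lr = config$learningRate, epochs = config$epochs,
                      batchSize = config$batchSize, seed = config$seed)
  structure(list(net = net, nChannels = ncol(x), config = config),
            class = c("nircalCNN", "nircalModel"))
}

#' Train the 1-D ResNet-18 regressor
#'
#' @inheritParams trainXGB
#' @param config a [resnetConfig()].
#' @return a fitted model handle for [predictMoisture()].
#' @export
trainResNet <- function(x, y, config = resnetConfig()) {
  stopifnot(inherits(config, "ResNetConfig"))
  x <- checkTrainingData(x, y)
  net <- trainNetwork(x, y,
                      build = function(len)
                        buildResNet1d(len, config$widths, config$stemKernel),
                      lr = config$learningRate, epochs = config$epochs,
                      batchSize = config$batchSize, seed = config$seed)
  structure(list(net = net, nChannels = ncol(x), config = config),
            class = c("nircalResNet", "nircalModel"))
}

setOldClass(c("nircalXGB", "nircalModel"))
setOldClass(c("nircalCNN", "nircalModel"))
setOldClass(c("nircalResNet", "nircalModel"))

checkChannels <- function(object, x) {
  if (ncol(x) != object$nChannels)
    stop(sprintf("x has %d channels, model was trained with %d",
                 ncol(x), object$nChannels))
}

#' @rdname predictMoisture
setMethod("predictMoisture", "nircalXGB", function(object, x) {
  x <- as.matrix(x)
  checkChannels(object, x)
  as.numeric(stats::predict(object$booster,
                            xgboost::xgb.DMatrix(x, nthread = 1)))
})

#' @rdname predictMoisture
setMethod("predictMoisture", "nircalCNN", function(object, x) {
  x <- as.matrix(x)
  checkChannels(object, x)
  predictNetwork(object$net, x)
})

#' @rdname predictMoisture
setMethod("predictMoisture", "nircalResNet", function(object, x) {
  x <- as.matrix(x)
  checkChannels(object, x)
  predictNetwork(object$net, x)
})

#' Build a PredictionSet from a fitted model
#'
#' @param model a fitted handle from [trainXGB()], [trainCNN()] or
#'   [trainResNet()].
#' @param x spectra matrix to predict on.
#' @param y aligned actual response values.
#' @param setLabel "train" or "test".
#' @param modelLabel model family label for the report grid.
#' @param wavelengthSetLabel "full" or "selected".
#' @return a [PredictionSet-class].
#' @export
makePredictionSet <- function(model, x, y, setLabel = "test",
                              modelLabel = "model",
                              wavelengthSetLabel = "full") {
  pred <- predictMoisture(model, x)
  if (length(pred) != length(y)) stop("prediction and y lengths differ")
  PredictionSet(y, pred, setLabel, modelLabel, wavelengthSetLabel)
}
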