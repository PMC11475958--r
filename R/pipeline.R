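# End-to-end orchestration of the six-run experiment grid:
# generate (or load) -> Savitzky-Golay first derivative -> SPXY split ->
# GA wavelength selection -> {XGB, CNN, ResNet} x {full, selected} ->
# GPR prediction intervals -> point/interval metric report.

#' Assemble a pipeline run configuration
#'
#' One global seed drives every stochastic stage through fixed offsets,
#' so a rerun with the same config reproduces the whole grid. Moisture is
#' modeled on the mass-fraction scale (percent / 100) and reported on
#' that scale in the grid; spectra files and SpectraSet objects keep
#' percent.
#'
#' @param generator a [generatorConfig()]; ignored when `spectraFile` is
#'   given.
#' @param spectraFile optional CSV of real spectra (see [readSpectra()])
#'   with a moisture_percent column; replaces the synthetic generator.
#' @param preprocessing an [sgParams()].
#' @param splitMethod "spxy" or "ks".
#' @param nTrain training-set size.
#' @param selection a [gaConfig()].
#' @param xgb,cnn,resnet regressor configs ([xgbConfig()], [cnnConfig()],
#'   [resnetConfig()]).
#' @param intervalConfidence nominal interval coverage (default 0.95).
#' @param calibrationProtocol "train" fits the GP calibration on
#'   training-set (prediction, actual) pairs only (no test-target
#'   leakage; the default); "pooled" fits on train + test pairs for
#'   reproduction of workflows that used both.
#' @param outputDir optional run directory for stage artifacts.
#' @param seed global integer seed, propagated to every stage.
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(generator = generatorConfig(),
                      spectraFile = NULL,
                      preprocessing = sgParams(),
                      splitMethod = c("spxy", "ks"),
                      nTrain = 300L,
                      selection = gaConfig(),
                      xgb = xgbConfig(),
                      cnn = cnnConfig(),
                      resnet = resnetConfig(),
                      intervalConfidence = 0.95,
                      calibrationProtocol = c("train", "pooled"),
                      outputDir = NULL,
                      seed = 1L) {
  splitMethod <- match.arg(splitMethod)
  calibrationProtocol <- match.arg(calibrationProtocol)
  seed <- as.integer(seed)
  # propagate the global seed into every stochastic sub-config
  generator$seed <- seed
  selection$seed <- seed + 10L
  xgb$seed <- seed + 20L
  cnn$seed <- seed + 30L
  resnet$seed <- seed + 40L
  structure(list(generator = generator, spectraFile = spectraFile,
                 preprocessing = preprocessing, splitMethod = splitMethod,
                 nTrain = as.integer(nTrain), selection = selection,
                 xgb = xgb, cnn = cnn, resnet = resnet,
                 intervalConfidence = intervalConfidence,
                 calibrationProtocol = calibrationProtocol,
                 outputDir = outputDir, seed = seed),
            class = "RunConfig")
}

stageLog <- function(log, name, t0) {
  elapsed <- as.numeric(Sys.time()) - t0
  message(sprintf("[nircal] stage %-12s %.1fs", name, elapsed))
  c(log, stats::setNames(elapsed, name))
}

writeArtifact <- function(dir, name, writer) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writer(file.path(dir, name))
  invisible(file.path(dir, name))
}

#' Run the six-model experiment grid end to end
#'
#' Executes generate (or load) -> preprocess -> split -> select ->
#' train x6 -> intervals x6 -> metrics, and returns the comparison
#' report: one row per model family and wavelength set with R2, RMSEP,
#' both RPD conventions, PICP, PINAW and CWC on the test set. When
#' `config$outputDir` is set, stage artifacts (spectra, split,
#' selection, per-cell predictions and intervals, report, manifest with
#' every seed) are persisted there. A stage failure aborts with the
#' stage name; artifacts of completed stages remain on disk.
#'
#' @param config a [runConfig()].
#' @return a list: `report` (the 6-row grid), `selection`
#'   ([SelectionResult-class]), `split` ([SplitResult-class]),
#'   `diagnostics` ([splitDiagnostics()]), `predictions` and `intervals`
#'   (per-cell lists), `timings`, `outputDir`.
#' @export
runExperiment <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  dir <- config$outputDir
  log <- numeric(0)
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log <<- stageLog(log, name, t0)
    out
  }

  raw <- stage("generate", {
    s <- if (!is.null(config$spectraFile)) readSpectra(config$spectraFile)
         else simulateSpectra(config$generator)
    if (is.null(moisture(s)))
      stop("input spectra carry no moisture reference values")
    writeArtifact(dir, "spectra.csv", function(p) writeSpectra(s, p))
    s
  })

  deriv <- stage("preprocess", {
    d <- sgFirstDerivative(raw, config$preprocessing)
    writeArtifact(dir, "derivative.csv", function(p) writeSpectra(d, p))
    d
  })

  x <- absorbance(deriv)
  yFrac <- moisture(deriv) / 100       # model on the mass-fraction scale

  split <- stage("split", {
    sp <- if (config$splitMethod == "spxy")
      spxySplit(x, yFrac, config$nTrain) else ksSplit(x, config$nTrain)
    writeArtifact(dir, "split.json", function(p)
      jsonlite::write_json(list(method = sp@method,
                                train = sp@trainIndices,
                                test = sp@testIndices), p))
    sp
  })
  tr <- trainIndices(split); te <- testIndices(split)
  diagnostics <- splitDiagnostics(split, moisture(deriv))

  selection <- stage("select", {
    sel <- gaSelect(x[tr, , drop = FALSE], yFrac[tr], config$selection,
                    wavelengthsNm = wavelengths(deriv))
    writeArtifact(dir, "selection.json", function(p)
      jsonlite::write_json(list(channels = sel@selectedChannels,
                                wavelengths_nm = sel@selectedWavelengths,
                                fitness = sel@fitnessHistory,
                                importance = sel@importance), p,
                           digits = NA))
    sel
  })

  channelSets <- list(full = seq_len(ncol(x)),
                      selected = selectedChannels(selection))
  trainers <- list(
    xgb = function(xm, ym) trainXGB(xm, ym, config$xgb),
    cnn = function(xm, ym) trainCNN(xm, ym, config$cnn),
    resnet = function(xm, ym) trainResNet(xm, ym, config$resnet))

  predictions <- list(); intervals <- list(); rows <- NULL
  for (wset in names(channelSets)) {
    cols <- channelSets[[wset]]
    for (mod in names(trainers)) {
      cell <- paste(mod, wset, sep = "_")
      fitted <- stage(paste0("train_", cell),
                      trainers[[mod]](x[tr, cols, drop = FALSE], yFrac[tr]))
      pTrain <- makePredictionSet(fitted, x[tr, cols, drop = FALSE],
                                  yFrac[tr], "train", mod, wset)
      pTest <- makePredictionSet(fitted, x[te, cols, drop = FALSE],
                                 yFrac[te], "test", mod, wset)
      predictions[[cell]] <- list(train = pTrain, test = pTest)

      iv <- stage(paste0("intervals_", cell), {
        calib <- if (config$calibrationProtocol == "train")
          fitGPR(pTrain@yPred, pTrain@yActual)
        else fitGPR(c(pTrain@yPred, pTest@yPred),
                    c(pTrain@yActual, pTest@yActual))
        predictInterval(calib, pTest@yPred, config$intervalConfidence)
      })
      intervals[[cell]] <- iv

      pm <- pointMetrics(pTest)
      im <- intervalMetrics(pTest@yActual, iv)
      rows <- rbind(rows, data.frame(
        wavelengthSet = wset, model = mod,
        r2 = pm$r2, rmsep = pm$rmsep, rpd = pm$rpdEq,
        rpdSdRatio = pm$rpdSdRatio,
        picp = im$picp, pinaw = im$pinaw, cwc = im$cwc,
        stringsAsFactors = FALSE))

      writeArtifact(dir, paste0("predictions_", cell, ".csv"), function(p)
        utils::write.csv(data.frame(set = c(rep("train", length(tr)),
                                            rep("test", length(te))),
                                    actual = c(pTrain@yActual, pTest@yActual),
                                    predicted = c(pTrain@yPred, pTest@yPred)),
                         p, row.names = FALSE))
      writeArtifact(dir, paste0("intervals_", cell, ".csv"), function(p)
        utils::write.csv(data.frame(actual = pTest@yActual, mu = iv@mu,
                                    sigma = iv@sigma, lower = iv@lower,
                                    upper = iv@upper),
                         p, row.names = FALSE))
    }
  }
  report <- rows

  stage("report", {
    writeArtifact(dir, "report.csv", function(p)
      utils::write.csv(report, p, row.names = FALSE))
    writeArtifact(dir, "selection_effect.csv", function(p)
      utils::write.csv(selectionEffectReport(report), p, row.names = FALSE))
    writeArtifact(dir, "manifest.json", function(p) {
      cfgFile <- tempfile(); saveRDS(config, cfgFile)
      jsonlite::write_json(list(
        seed = config$seed,
        stageSeeds = list(generator = config$generator$seed,
                          selection = config$selection$seed,
                          xgb = config$xgb$seed, cnn = config$cnn$seed,
                          resnet = config$resnet$seed),
        splitMethod = config$splitMethod, nTrain = config$nTrain,
        calibrationProtocol = config$calibrationProtocol,
        configHash = unname(tools::md5sum(cfgFile)),
        timings = as.list(log)), p, auto_unbox = TRUE)
      unlink(cfgFile)
    })
    NULL
  })

  list(report = report, selection = selection, split = split,
       diagnostics = diagnostics, predictions = predictions,
       intervals = intervals, timings = log, outputDir = dir)
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML document onto [runConfig()]: top-level keys
#' `generator`, `preprocessing`, `split` (method, n_train), `selection`,
#' `xgb`, `cnn`, `resnet`, `uncertainty` (confidence, protocol),
#' `output_dir`, `seed`. Unknown keys raise an error; omitted ones take
#' the package defaults.
#'
#' @param path YAML file path.
#' @return a [runConfig()] list.
#' @export
readRunConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("generator", "preprocessing", "split", "selection", "xgb",
             "cnn", "resnet", "uncertainty", "output_dir", "seed",
             "spectra_file")
  bad <- setdiff(names(doc), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  `%||%` <- function(a, b) if (is.null(a)) b else a
  fill <- function(fun, args) do.call(fun, as.list(args %||% list()))
  runConfig(
    generator = fill(generatorConfig, doc$generator),
    spectraFile = doc$spectra_file,
    preprocessing = fill(sgParams, doc$preprocessing),
    splitMethod = doc$split$method %||% "spxy",
    nTrain = doc$split$n_train %||% 300L,
    selection = fill(gaConfig, doc$selection),
    xgb = fill(xgbConfig, doc$xgb),
    cnn = fill(cnnConfig, doc$cnn),
    resnet = fill(resnetConfig, doc$resnet),
    intervalConfidence = doc$uncertainty$confidence %||% 0.95,
    calibrationProtocol = doc$uncertainty$protocol %||% "train",
    outputDir = doc$output_dir,
    seed = doc$seed %||% 1L)
}
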