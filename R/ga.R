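# Genetic-algorithm wavelength selection. Chromosomes are binary channel
# masks scored by the negative cross-validated MSE of a PLS regression
# restricted to the masked channels; selection is by tournament, with
# uniform crossover, per-bit mutation and elitism.

#' Configure the genetic wavelength selector
#'
#' @param populationSize chromosomes per generation.
#' @param nGenerations number of generations.
#' @param crossoverRate probability a parent pair undergoes uniform
#'   crossover (otherwise copied).
#' @param mutationRate per-bit flip probability.
#' @param elitismCount chromosomes carried over unchanged each generation;
#'   must be < populationSize.
#' @param minSelected minimum number of active channels; chromosomes below
#'   it are repaired by activating random bits.
#' @param plsComponents latent components of the PLS fitness model (capped
#'   at the size of the masked channel set).
#' @param cvFolds folds of the fitness cross-validation.
#' @param tournamentSize parent-selection tournament size.
#' @param initDensity expected fraction of active bits in random initial
#'   chromosomes; the all-ones chromosome is always included so the
#'   selected set can never score worse than the full mask on the
#'   training CV criterion.
#' @param seed integer seed; the whole GA run is deterministic given it.
#' @return a validated list of class "GAConfig".
#' @export
gaConfig <- function(populationSize = 100L, nGenerations = 50L,
                     crossoverRate = 0.8, mutationRate = 0.02,
                     elitismCount = 2L, minSelected = 5L,
                     plsComponents = 8L, cvFolds = 5L,
                     tournamentSize = 3L, initDensity = 0.3,
                     seed = 1L) {
  cfg <- list(populationSize = as.integer(populationSize),
              nGenerations = as.integer(nGenerations),
              crossoverRate = crossoverRate, mutationRate = mutationRate,
              elitismCount = as.integer(elitismCount),
              minSelected = as.integer(minSelected),
              plsComponents = as.integer(plsComponents),
              cvFolds = as.integer(cvFolds),
              tournamentSize = as.integer(tournamentSize),
              initDensity = initDensity, seed = as.integer(seed))
  if (cfg$crossoverRate < 0 || cfg$crossoverRate > 1 ||
      cfg$mutationRate < 0 || cfg$mutationRate > 1)
    stop("rates must lie in [0, 1]")
  if (cfg$elitismCount >= cfg$populationSize)
    stop("elitismCount must be < populationSize")
  if (cfg$minSelected < 1L) stop("minSelected must be >= 1")
  if (cfg$populationSize < 2L) stop("populationSize must be >= 2")
  structure(cfg, class = "GAConfig")
}

#' PLS cross-validation fitness of a channel mask
#'
#' Returns the negative mean k-fold cross-validated squared prediction
#' error of a PLS regression restricted to the masked channels (higher is
#' better). Infeasible masks (fewer active channels than
#' `max(minSelected, 1)`) return `-Inf` rather than raising, so the GA
#' can score them mid-run.
#'
#' @param mask logical or 0/1 vector over channels.
#' @param x preprocessed spectra matrix (samples x channels).
#' @param y aligned response vector.
#' @param config a [gaConfig()].
#' @param folds optional precomputed fold assignment (from the config seed
#'   when omitted); a shared assignment makes fitness comparable across
#'   masks.
#' @return scalar fitness (negative CV-MSE), or `-Inf` for infeasible masks.
#' @export
plsFitness <- function(mask, x, y, config = gaConfig(), folds = NULL) {
  mask <- as.logical(mask)
  nsel <- sum(mask)
  if (nsel < max(config$minSelected, 1L)) return(-Inf)
  if (is.null(folds)) folds <- cvFolds(length(y), config$cvFolds, config$seed)
  nc <- min(config$plsComponents, nsel)
  -plsCvMse(x[, mask, drop = FALSE], y, nc, folds)
}

# Ensure a mask has at least minSelected active bits (random repair).
repairMask <- function(mask, minSelected) {
  deficit <- minSelected - sum(mask)
  if (deficit > 0L) {
    off <- which(!mask)
    mask[off[sample.int(length(off), deficit)]] <- TRUE
  }
  mask
}

#' Genetic-algorithm wavelength selection
#'
#' Runs a seeded GA over binary channel masks with the cross-validated
#' PLS fitness of [plsFitness()]: tournament selection, uniform crossover,
#' per-bit mutation, and elitism. The initial population holds random
#' masks plus the all-ones chromosome, and the best chromosome ever seen
#' is returned, so the result can never score below the full mask on the
#' training CV criterion. Fully reproducible for a fixed config.
#'
#' @param x preprocessed training spectra (samples x channels).
#' @param y aligned response vector.
#' @param config a [gaConfig()].
#' @param wavelengthsNm optional channel wavelengths in nm for reporting;
#'   channel indices are used when omitted.
#' @return a [SelectionResult-class]; its importance slot carries
#'   standardized PLS coefficients from [wavelengthImportance()].
#' @export
gaSelect <- function(x, y, config = gaConfig(), wavelengthsNm = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  p <- ncol(x)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  if (is.null(wavelengthsNm)) wavelengthsNm <- seq_len(p)
  if (length(wavelengthsNm) != p)
    stop("wavelengthsNm must have one entry per channel")
  cfg <- config
  folds <- cvFolds(length(y), cfg$cvFolds, cfg$seed)
  cache <- new.env(parent = emptyenv())
  evalMask <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- plsFitness(mask, x, y, cfg, folds)
    cache[[key]] <- f
    f
  }
  withLocalSeed(cfg$seed, {
    pop <- lapply(seq_len(cfg$populationSize - 1L), function(i)
      repairMask(stats::runif(p) < cfg$initDensity, cfg$minSelected))
    pop <- c(pop, list(rep(TRUE, p)))
    fit <- vapply(pop, evalMask, numeric(1))
    bestMask <- pop[[which.max(fit)]]
    bestFit <- max(fit)
    history <- numeric(cfg$nGenerations)
    for (g in seq_len(cfg$nGenerations)) {
      ord <- order(fit, decreasing = TRUE)
      newPop <- pop[ord[seq_len(cfg$elitismCount)]]
      tournament <- function() {
        cand <- sample.int(cfg$populationSize, cfg$tournamentSize)
        pop[[cand[which.max(fit[cand])]]]
      }
      while (length(newPop) < cfg$populationSize) {
        p1 <- tournament(); p2 <- tournament()
        if (stats::runif(1) < cfg$crossoverRate) {
          swap <- stats::runif(p) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          flip <- stats::runif(p) < cfg$mutationRate
          child <- xor(child, flip)
          child <- repairMask(child, cfg$minSelected)
          if (length(newPop) < cfg$populationSize)
            newPop[[length(newPop) + 1L]] <- child
        }
      }
      pop <- newPop
      fit <- vapply(pop, evalMask, numeric(1))
      if (max(fit) > bestFit) {
        bestFit <- max(fit)
        bestMask <- pop[[which.max(fit)]]
      }
      history[g] <- bestFit
    }
    sel <- which(bestMask)
    imp <- wavelengthImportance(x[, sel, drop = FALSE], y,
                                min(cfg$plsComponents, length(sel)))
    new("SelectionResult",
        selectedChannels = as.integer(sel),
        selectedWavelengths = as.numeric(wavelengthsNm[sel]),
        fitnessHistory = history,
        importance = imp)
  })
}

#' Standardized PLS coefficients as wavelength importance
#'
#' Fits a PLS regression on standardized predictors so coefficient
#' magnitudes are comparable across channels; larger magnitude means a
#' larger contribution to the moisture prediction.
#'
#' @param xSelected spectra restricted to the channels of interest.
#' @param y aligned response vector.
#' @param plsComponents latent components; reduced automatically (with a
#'   warning) when they exceed the predictor rank.
#' @return numeric coefficient vector, one per column of `xSelected`.
#' @export
wavelengthImportance <- function(xSelected, y, plsComponents = 8L) {
  xSelected <- as.matrix(xSelected)
  if (ncol(xSelected) < 1L) stop("no channels selected")
  fit <- plsFit(xSelected, y, plsComponents, scale = TRUE)
  unname(fit$coefficients)
}
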