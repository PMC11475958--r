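# Savitzky-Golay smoothing combined with the first derivative: one
# convolution pass fits a local polynomial of order `polyorder` in a
# `windowLength`-channel window and evaluates its first derivative, which
# simultaneously suppresses channel noise and removes additive baselines.

#' Savitzky-Golay derivative parameters
#'
#' @param windowLength odd window size in channels; must exceed `polyorder`.
#' @param polyorder local polynomial order (>= 1).
#' @return a validated list of class "SGParams". The derivative order is
#'   fixed at 1 (the combined smoothing + first-derivative treatment).
#' @export
sgParams <- function(windowLength = 11L, polyorder = 2L) {
  windowLength <- as.integer(windowLength)
  polyorder <- as.integer(polyorder)
  if (windowLength %% 2L != 1L) stop("windowLength must be odd")
  if (polyorder < 1L) stop("polyorder must be >= 1")
  if (windowLength <= polyorder)
    stop("windowLength must be greater than polyorder")
  structure(list(windowLength = windowLength, polyorder = polyorder,
                 derivOrder = 1L), class = "SGParams")
}

#' Savitzky-Golay smoothed first derivative of spectra
#'
#' Applies a single-pass Savitzky-Golay first-derivative filter to every
#' spectrum. The wavelength grid must be uniform; the output is in
#' absorbance per nm, the same shape as the input, with boundary values
#' obtained from polynomial fits at the edges (no truncation). The
#' moisture vector, when present, is passed through unchanged.
#'
#' Properties: exact on polynomials up to `polyorder` at interior points,
#' and invariant to additive constants (`sg(A + c) = sg(A)`), which is the
#' baseline-removal purpose of the treatment.
#'
#' @param set a [SpectraSet-class].
#' @param params an [sgParams()] object.
#' @return a [SpectraSet-class] of derivative spectra.
#' @examples
#' s <- simulateSpectra(generatorConfig(nSamples = 5, seed = 2))
#' d <- sgFirstDerivative(s, sgParams(11, 2))
#' dim(absorbance(d))
#' @export
sgFirstDerivative <- function(set, params = sgParams()) {
  stopifnot(is(set, "SpectraSet"), inherits(params, "SGParams"))
  wl <- wavelengths(set)
  if (length(wl) < params$windowLength)
    stop(sprintf("spectrum has %d channels but the window needs %d",
                 length(wl), params$windowLength))
  dwl <- diff(wl)
  delta <- mean(dwl)
  if (any(abs(dwl - delta) > 1e-6 * abs(delta)))
    stop("wavelength grid is not uniform; Savitzky-Golay filtering needs ",
         "equally spaced channels")
  ab <- absorbance(set)
  out <- t(apply(ab, 1L, signal::sgolayfilt, p = params$polyorder,
                 n = params$windowLength, m = params$derivOrder,
                 ts = delta))
  if (nrow(ab) == 1L) out <- matrix(out, nrow = 1L)
  SpectraSet(out, wl, moisture(set))
}
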