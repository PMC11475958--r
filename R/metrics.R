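# Point metrics (R2, RMSEP, RPD) and interval metrics (PICP, PINAW, CWC).
# Conventions deliberately follow the field's printed definitions: RMSEP
# divides by n - 1; PICP uses strict inequalities; PINAW normalizes mean
# absolute interval width by the reference range; CWC = PICP / PINAW.

#' Coefficient of determination
#'
#' `1 - sum((actual - pred)^2) / sum((actual - mean(actual))^2)`. The
#' denominator is centered on the mean of the actual values (a constant
#' predictor at that mean scores exactly 0).
#'
#' @param p a [PredictionSet-class].
#' @return scalar R2 (<= 1; negative when worse than the mean predictor).
#' @examples
#' rSquared(PredictionSet(c(1, 2, 3), c(1, 2, 4)))  # 0.5
#' @export
rSquared <- function(p) {
  stopifnot(is(p, "PredictionSet"))
  y <- p@yActual; yhat <- p@yPred
  if (length(y) < 2L) stop("need at least 2 samples")
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop("zero variance in actual values; R2 undefined")
  1 - sum((y - yhat)^2) / ss
}

#' Root mean square error of prediction (n - 1 variant)
#'
#' `sqrt(sum((actual - pred)^2) / (n - 1))`, the printed convention of
#' this workflow (an n - 1 rather than n divisor).
#'
#' @param p a [PredictionSet-class].
#' @return scalar RMSEP (>= 0).
#' @export
rmsep <- function(p) {
  stopifnot(is(p, "PredictionSet"))
  n <- length(p@yActual)
  if (n < 2L) stop("need at least 2 samples")
  sqrt(sum((p@yActual - p@yPred)^2) / (n - 1))
}

#' Ratio of performance to deviation, R2 form
#'
#' `1 / sqrt(1 - R2)`: the RPD form derived from the coefficient of
#' determination. A value above 3 is the usual screening-quality bar.
#' Returns `Inf` at R2 = 1.
#'
#' @param r2 coefficient of determination (< 1 for a finite result).
#' @return scalar RPD.
#' @examples
#' rpd(0.75)  # 2
#' @export
rpd <- function(r2) {
  if (r2 > 1) stop("r2 must be <= 1")
  if (r2 == 1) return(Inf)
  1 / sqrt(1 - r2)
}

#' Ratio of performance to deviation, SD/RMSEP convention
#'
#' The classical chemometric convention: SD of the actual values divided
#' by the RMSEP. Both RPD conventions are reported side by side because
#' published grids do not always state which was used.
#'
#' @param p a [PredictionSet-class].
#' @return scalar RPD.
#' @export
rpdSD <- function(p) {
  stopifnot(is(p, "PredictionSet"))
  stats::sd(p@yActual) / rmsep(p)
}

#' Prediction interval coverage probability
#'
#' Fraction of observations strictly inside their intervals
#' (`lower < y < upper`; a value exactly on a bound counts as outside).
#'
#' @param y actual values, aligned with the interval.
#' @param interval a [PredictionInterval-class].
#' @return scalar in [0, 1].
#' @export
picp <- function(y, interval) {
  stopifnot(is(interval, "PredictionInterval"))
  if (length(y) != length(interval@lower))
    stop(sprintf("y has length %d, interval has %d",
                 length(y), length(interval@lower)))
  mean(interval@lower < y & y < interval@upper)
}

#' Prediction interval normalized average width
#'
#' Mean absolute interval width divided by the range `R` of the actual
#' values: `sum(|U_i - L_i|) / (N * R)`.
#'
#' @param y actual values (used for the normalization range unless
#'   `range` is given).
#' @param interval a [PredictionInterval-class].
#' @param range optional normalization range R; defaults to
#'   `max(y) - min(y)`, which must be > 0.
#' @return scalar PINAW (>= 0).
#' @export
pinaw <- function(y, interval, range = NULL) {
  stopifnot(is(interval, "PredictionInterval"))
  if (length(y) != length(interval@lower))
    stop(sprintf("y has length %d, interval has %d",
                 length(y), length(interval@lower)))
  R <- if (is.null(range)) max(y) - min(y) else range
  if (R <= 0) stop("normalization range is zero; PINAW undefined")
  mean(abs(interval@upper - interval@lower)) / R
}

#' Coverage width criterion
#'
#' `CWC = PICP / PINAW`: higher means tighter intervals at equal
#' coverage. `Inf` when PINAW is 0.
#'
#' @param picpValue,pinawValue the two interval metrics.
#' @return scalar CWC.
#' @examples
#' cwc(1.000, 1.080)  # 0.926
#' @export
cwc <- function(picpValue, pinawValue) {
  if (pinawValue < 0) stop("pinaw must be >= 0")
  if (pinawValue == 0) return(Inf)
  picpValue / pinawValue
}

#' Percent change between two metric values
#'
#' Published comparisons mix three conventions, so the convention is an
#' explicit argument: "increase_vs_old" = 100 (new - old)/old;
#' "decrease_vs_old" = 100 (old - new)/old;
#' "reduction_vs_new" = 100 (old - new)/new.
#'
#' @param old,new the two values being compared.
#' @param convention one of the three labels above.
#' @return signed percent change under the requested convention.
#' @examples
#' relativeChange(0.582, 0.920, "increase_vs_old")  # 58.1
#' relativeChange(0.019, 0.008, "reduction_vs_new")  # 137.5
#' @export
relativeChange <- function(old, new,
                           convention = c("increase_vs_old",
                                          "decrease_vs_old",
                                          "reduction_vs_new")) {
  convention <- match.arg(convention)
  denom <- switch(convention, reduction_vs_new = new, old)
  if (denom == 0) stop("zero denominator for convention ", convention)
  switch(convention,
         increase_vs_old = 100 * (new - old) / old,
         decrease_vs_old = 100 * (old - new) / old,
         reduction_vs_new = 100 * (old - new) / new)
}

#' All point metrics of a prediction set
#'
#' @param p a [PredictionSet-class].
#' @return a one-row data.frame: r2, rmsep, rpdEq (1/sqrt(1 - R2) form),
#'   rpdSdRatio (SD/RMSEP form), n.
#' @export
pointMetrics <- function(p) {
  r2 <- rSquared(p)
  data.frame(r2 = r2, rmsep = rmsep(p), rpdEq = rpd(r2),
             rpdSdRatio = rpdSD(p), n = length(p@yActual))
}

#' All interval metrics of a prediction interval
#'
#' @param y actual values aligned with the interval.
#' @param interval a [PredictionInterval-class].
#' @param range optional normalization range for PINAW.
#' @return a one-row data.frame: picp, pinaw, cwc, range, n.
#' @export
intervalMetrics <- function(y, interval, range = NULL) {
  pc <- picp(y, interval)
  pw <- pinaw(y, interval, range)
  R <- if (is.null(range)) max(y) - min(y) else range
  data.frame(picp = pc, pinaw = pw, cwc = cwc(pc, pw), range = R,
             n = length(y))
}
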