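# SPXY / Kennard-Stone sample-set partitioning. Both use the same greedy
# max-min selection; SPXY measures the joint, normalized spectral (x) and
# chemical (y) distance d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy), while
# KS uses the spectral term alone.

# Greedy max-min selection on a precomputed distance matrix.
# Ties broken by lowest index (seed pair: smallest i, then smallest j).
maxMinSelect <- function(d, nTrain) {
  n <- nrow(d)
  if (nTrain == n) return(seq_len(n))
  # seed with the most distant pair
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (nrow(best) == 0L) best <- matrix(c(1L, 2L), 1)  # all-zero distances
  ord <- order(best[, 1], best[, 2])
  sel <- as.integer(best[ord[1], ])
  minDist <- pmin(d[, sel[1]], d[, sel[2]])
  minDist[sel] <- -Inf
  while (length(sel) < nTrain) {
    nxt <- which.max(minDist)  # which.max returns the first (lowest) index
    sel <- c(sel, nxt)
    minDist <- pmin(minDist, d[, nxt])
    minDist[nxt] <- -Inf
  }
  as.integer(sort(unname(sel)))
}

normalizedDist <- function(m, label) {
  d <- as.matrix(stats::dist(m))
  mx <- max(d)
  if (mx == 0) {
    warning(sprintf("all %s distances are zero; the %s term is dropped",
                    label, label))
    return(d)  # all zeros
  }
  d / mx
}

#' SPXY train/test partitioning
#'
#' Selects a representative training set by greedy max-min selection on
#' the joint distance `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)` with
#' Euclidean spectral distance dx and absolute chemical distance dy.
#' The training set is seeded with the pair maximizing d and grown by
#' adding the candidate whose minimum distance to the current training
#' set is largest, until `nTrain` samples are selected. Fully
#' deterministic; distance ties are broken by lowest sample index.
#'
#' @param x numeric spectra matrix (samples x channels), typically
#'   preprocessed.
#' @param y numeric reference vector (moisture), aligned with `x` rows.
#' @param nTrain requested training-set size, in [2, nrow(x)].
#' @return a [SplitResult-class].
#' @examples
#' sp <- spxySplit(matrix(0:2), c(0, 1, 2), 2)
#' trainIndices(sp)
#' @export
spxySplit <- function(x, y, nTrain) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  nTrain <- as.integer(nTrain)
  if (nTrain < 2L || nTrain > nrow(x))
    stop("nTrain must be in [2, n samples]")
  d <- normalizedDist(x, "spectral") + normalizedDist(cbind(y), "chemical")
  sel <- maxMinSelect(d, nTrain)
  new("SplitResult", trainIndices = sel,
      testIndices = setdiff(seq_len(nrow(x)), sel),
      method = "spxy", nTrain = nTrain)
}

#' Kennard-Stone train/test partitioning
#'
#' Identical max-min selection to [spxySplit()] but on the spectral
#' distance alone; provided as the comparison baseline SPXY extends.
#'
#' @inheritParams spxySplit
#' @return a [SplitResult-class].
#' @export
ksSplit <- function(x, nTrain) {
  x <- as.matrix(x)
  nTrain <- as.integer(nTrain)
  if (nTrain < 2L || nTrain > nrow(x))
    stop("nTrain must be in [2, n samples]")
  d <- normalizedDist(x, "spectral")
  sel <- maxMinSelect(d, nTrain)
  new("SplitResult", trainIndices = sel,
      testIndices = setdiff(seq_len(nrow(x)), sel),
      method = "ks", nTrain = nTrain)
}

#' Diagnostics for a train/test split
#'
#' Reports whether the test-set reference range falls within the
#' training-set range (a common sanity check for representative
#' partitioning), plus summary statistics per set. Reported, not
#' asserted: max-min selection tends to place extremes in the training
#' set but does not guarantee it.
#'
#' @param split a [SplitResult-class].
#' @param y reference vector aligned with the original sample order.
#' @return a list with per-set summaries and `testWithinTrainRange`.
#' @export
splitDiagnostics <- function(split, y) {
  stopifnot(is(split, "SplitResult"))
  yTr <- y[trainIndices(split)]
  yTe <- y[testIndices(split)]
  summ <- function(v) c(n = length(v), mean = mean(v), min = min(v),
                        max = max(v), sd = stats::sd(v))
  list(train = summ(yTr), test = summ(yTe),
       testWithinTrainRange = length(yTe) == 0 ||
         (min(yTe) >= min(yTr) && max(yTe) <= max(yTr)))
}
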