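## Metric mathematics: predictive mean / entropy, certainty partitioning,
## both confusion matrices, uncertainty-aware metrics, calibration, AUC-ROC
## and percentage-uncertainty deltas.

#' Predictive mean over stochastic forward passes
#'
#' Element-wise arithmetic mean of the per-pass positive-class probabilities:
#' the Monte Carlo estimate of the posterior predictive probability.
#'
#' @param samples a [ProbabilitySample-class].
#' @return numeric vector of per-instance means in [0, 1].
#' @examples
#' predictiveMean(probabilitySample(c(0.2, 0.4, 0.6)))  # 0.4
#' @export
predictiveMean <- function(samples) {
  stopifnot(is(samples, "ProbabilitySample"))
  colMeans(samples@probs)
}

#' Predictive entropy of a class-probability distribution
#'
#' Shannon entropy \eqn{-\sum_c p_c \log p_c} in nats, with the convention
#' \eqn{0 \log 0 = 0}. Bounded by \eqn{\log C}; zero exactly at degenerate
#' distributions and maximal at the uniform one. Small predictive entropy
#' means a confident predictive distribution.
#'
#' @param p numeric vector of class probabilities (must be non-negative and
#'   sum to 1 within `tol`).
#' @param tol tolerance on the sum-to-one check.
#' @return entropy in nats.
#' @examples
#' predictiveEntropy(c(0.5, 0.5))  # log(2)
#' predictiveEntropy(c(1, 0))     # 0
#' @export
predictiveEntropy <- function(p, tol = 1e-8) {
  if (length(p) < 1L || anyNA(p) || any(p < 0))
    stop("invalid distribution: probabilities must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("invalid distribution: probabilities must sum to 1 (got ",
         format(sum(p)), ")")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

## vectorised two-point entropy of (mu, 1 - mu), in nats
binaryEntropy <- function(mu) {
  h <- numeric(length(mu))
  for (side in list(mu, 1 - mu)) {
    nz <- side > 0
    h[nz] <- h[nz] - side[nz] * log(side[nz])
  }
  h
}

#' Partition instances into certain and uncertain
#'
#' An instance is uncertain iff its normalised predictive entropy strictly
#' exceeds the threshold; boundary instances count as certain. The threshold
#' acts on entropy normalised by \eqn{\log C}, so the conventional 0.30
#' cut-off is scale-free in the class count.
#'
#' @param entropyNorm numeric vector of normalised entropies in [0, 1].
#' @param threshold scalar in [0, 1].
#' @return logical vector, TRUE = certain.
#' @export
partitionCertainty <- function(entropyNorm, threshold = 0.30) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("invalid parameter: threshold must be a scalar in [0, 1]")
  entropyNorm <= threshold
}

#' Summarise a ProbabilitySample for one binary OvA task
#'
#' Computes the per-instance predictive mean, the predictive entropy of the
#' two-point predictive distribution (mu, 1 - mu) in nats, its normalised
#' version (entropy / log 2), the hard label (positive iff mu >= 0.5) and the
#' certainty flag at `threshold`.
#'
#' @param samples a [ProbabilitySample-class].
#' @param threshold certainty threshold on normalised entropy (default 0.30).
#' @return a [PredictiveSummary-class].
#' @export
summarizePredictions <- function(samples, threshold = 0.30) {
  mu <- predictiveMean(samples)
  h <- binaryEntropy(mu)
  hn <- pmin(h / log(2), 1)
  new("PredictiveSummary", muPred = mu, entropy = h, entropyNorm = hn,
      predictedLabel = as.integer(mu >= 0.5),
      certain = partitionCertainty(hn, threshold),
      threshold = threshold)
}

#' Uncertainty confusion matrix from correctness and certainty
#'
#' Tallies the four correctness-by-certainty outcomes: TC = correct and
#' certain, TU = incorrect and uncertain (the two desirable cells), FC =
#' incorrect but certain, FU = correct but uncertain.
#'
#' @param predicted integer/numeric vector of 0/1 predicted labels.
#' @param truth integer/numeric vector of 0/1 true labels.
#' @param certain logical vector of certainty flags.
#' @return an [UncertaintyConfusionMatrix-class].
#' @export
uncertaintyConfusion <- function(predicted, truth, certain) {
  n <- length(truth)
  if (length(predicted) != n || length(certain) != n)
    stop("invalid input: predicted, truth and certain must have equal length")
  if (anyNA(predicted) || anyNA(truth) || anyNA(certain))
    stop("invalid input: NA values")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("invalid input: labels must be binary 0/1")
  correct <- predicted == truth
  new("UncertaintyConfusionMatrix",
      TC = sum(correct & certain), TU = sum(!correct & !certain),
      FC = sum(!correct & certain), FU = sum(correct & !certain))
}

zeroRatio <- function(num, den) if (den == 0) 0 else num / den

#' Uncertainty-aware metrics from an uncertainty confusion matrix
#'
#' \describe{
#'   \item{uSens}{TU / (TU + FC): the model's power to flag its own errors as
#'     uncertain.}
#'   \item{uSpec}{TC / (TC + FU): certainty on correct predictions.}
#'   \item{uPrec}{TU / (TU + FU): how often an uncertainty flag marks a real
#'     error.}
#'   \item{uAcc}{(TC + TU) / n: overall reliability of the certainty signal.}
#'   \item{uF1}{harmonic mean of uPrec and uSens.}
#' }
#' Ratios with zero denominator return 0 and raise the `degenerate` flag so
#' sweeps never abort.
#'
#' @param cm an [UncertaintyConfusionMatrix-class].
#' @return named list: `uSens`, `uSpec`, `uPrec`, `uAcc`, `uF1`,
#'   `degenerate` (logical).
#' @export
uncertaintyMetrics <- function(cm) {
  stopifnot(is(cm, "UncertaintyConfusionMatrix"))
  TC <- cm@TC; TU <- cm@TU; FC <- cm@FC; FU <- cm@FU
  n <- TC + TU + FC + FU
  if (n < 1L) stop("invalid input: empty confusion matrix")
  uSens <- zeroRatio(TU, TU + FC)
  uSpec <- zeroRatio(TC, TC + FU)
  uPrec <- zeroRatio(TU, TU + FU)
  uAcc <- (TU + TC) / n
  uF1 <- zeroRatio(2 * uPrec * uSens, uPrec + uSens)
  degenerate <- (TU + FC) == 0L || (TC + FU) == 0L || (TU + FU) == 0L ||
    (uPrec + uSens) == 0
  list(uSens = uSens, uSpec = uSpec, uPrec = uPrec, uAcc = uAcc, uF1 = uF1,
       degenerate = degenerate)
}

#' Binary confusion matrix from predicted and true labels
#'
#' @param predicted,truth 0/1 label vectors of equal length.
#' @return a [BinaryConfusionMatrix-class].
#' @export
binaryConfusion <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("invalid input: length mismatch")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("invalid input: labels must be binary 0/1")
  new("BinaryConfusionMatrix",
      TP = sum(predicted == 1 & truth == 1),
      TN = sum(predicted == 0 & truth == 0),
      FP = sum(predicted == 1 & truth == 0),
      FN = sum(predicted == 0 & truth == 1))
}

#' Traditional classification metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/n, precision = TP/(TP+FP) and the F1 score as the harmonic mean
#' of precision and sensitivity. Zero-denominator ratios return 0 and raise
#' the `degenerate` flag.
#'
#' @param cm a [BinaryConfusionMatrix-class].
#' @return named list: `sensitivity`, `specificity`, `accuracy`, `precision`,
#'   `f1`, `degenerate`.
#' @export
traditionalMetrics <- function(cm) {
  stopifnot(is(cm, "BinaryConfusionMatrix"))
  TP <- cm@TP; TN <- cm@TN; FP <- cm@FP; FN <- cm@FN
  n <- TP + TN + FP + FN
  if (n < 1L) stop("invalid input: empty confusion matrix")
  sens <- zeroRatio(TP, TP + FN)
  spec <- zeroRatio(TN, TN + FP)
  prec <- zeroRatio(TP, TP + FP)
  acc <- (TP + TN) / n
  f1 <- zeroRatio(2 * prec * sens, prec + sens)
  degenerate <- (TP + FN) == 0L || (TN + FP) == 0L || (TP + FP) == 0L ||
    (prec + sens) == 0
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       precision = prec, f1 = f1, degenerate = degenerate)
}

#' Expected calibration error
#'
#' Confidence per instance is `max(mu, 1 - mu)`; instances are placed into
#' `M` equal-width confidence bins on [0, 1] (first bin closed at its left
#' edge, the rest left-open). Per bin, accuracy is the fraction of instances
#' whose hard label (mu >= 0.5) matches the truth and confidence is the mean
#' confidence; the ECE is the bin-count-weighted mean absolute gap
#' \eqn{\sum_m \frac{|B_m|}{n} |acc(B_m) - conf(B_m)|}. Empty bins
#' contribute 0.
#'
#' @param mu numeric vector of predictive-mean probabilities.
#' @param truth 0/1 label vector.
#' @param bins number of bins `M` (default 10).
#' @return list with `ece` (scalar) and `table`, a per-bin data.frame with
#'   columns `bin`, `lower`, `upper`, `count`, `accuracy`, `confidence`.
#' @export
ece <- function(mu, truth, bins = 10L) {
  if (length(bins) != 1L || is.na(bins) || bins < 1L)
    stop("invalid parameter: bins must be >= 1")
  if (length(mu) != length(truth)) stop("invalid input: length mismatch")
  bins <- as.integer(bins)
  conf <- pmax(mu, 1 - mu)
  correct <- as.integer(mu >= 0.5) == truth
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- findInterval(conf, edges, left.open = TRUE, rightmost.closed = TRUE)
  idx[conf <= edges[2L]] <- 1L   # first bin closed on the left
  n <- length(mu)
  count <- tabulate(idx, nbins = bins)
  acc <- conf_mean <- rep(NA_real_, bins)
  gap <- 0
  for (m in seq_len(bins)) {
    if (count[m] == 0L) next
    inB <- idx == m
    acc[m] <- mean(correct[inB])
    conf_mean[m] <- mean(conf[inB])
    gap <- gap + count[m] / n * abs(acc[m] - conf_mean[m])
  }
  list(ece = gap,
       table = data.frame(bin = seq_len(bins), lower = edges[-(bins + 1L)],
                          upper = edges[-1L], count = count, accuracy = acc,
                          confidence = conf_mean))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' lower is better calibrated and more accurate.
#'
#' @param mu numeric vector of probabilities.
#' @param truth 0/1 label vector.
#' @return scalar in [0, 1].
#' @export
brierScore <- function(mu, truth) {
  if (length(mu) != length(truth)) stop("invalid input: length mismatch")
  mean((mu - truth)^2)
}

#' AUC-ROC by the rank (Mann-Whitney) formulation
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, counting ties as 1/2.
#'
#' @param scores numeric vector.
#' @param truth 0/1 label vector; both classes must be present.
#' @return scalar in [0, 1].
#' @export
aucROC <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("invalid input: length mismatch")
  nPos <- sum(truth == 1)
  nNeg <- sum(truth == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("undefined AUC: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Percentage uncertainty between a traditional and an uncertainty-aware metric
#'
#' The absolute difference, in percentage points, between a metric of the
#' plain (deterministic) classifier and its uncertainty-aware counterpart.
#' Both inputs are expected on the 0-100 scale. Reporting convention is one
#' decimal place; pass `digits = NA` to keep full precision.
#'
#' @param traditionalPct scalar, traditional metric in percent.
#' @param uqPct scalar, uncertainty-aware metric in percent.
#' @param digits decimals for reporting (default 1; `NA` = no rounding).
#' @return absolute difference in percentage points.
#' @examples
#' percentageUncertainty(92.8, 81.0)  # 11.8
#' @export
percentageUncertainty <- function(traditionalPct, uqPct, digits = 1L) {
  d <- abs(traditionalPct - uqPct)
  if (is.na(digits)) d else round(d, digits)
}
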