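#' ProbabilitySample: per-pass positive-class probabilities
#'
#' Container for the raw output of a stochastic predictor: a `T x n` matrix
#' whose entry `[t, i]` is the positive-class probability assigned to
#' instance `i` on stochastic forward pass `t`. Averaging over rows gives the
#' predictive mean; the spread over rows carries the epistemic component of
#' the predictive uncertainty.
#'
#' @slot probs numeric matrix, `T` passes by `n` instances, entries in [0, 1].
#' @seealso [probabilitySample()], [predictiveMean()], [summarizePredictions()]
#' @export
setClass("ProbabilitySample", representation(probs = "matrix"),
  validity = function(object) {
    p <- object@probs
    if (!is.numeric(p)) return("probs must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L)
      return("need at least one pass and one instance")
    if (anyNA(p)) return("probs contains NA")
    if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0, 1]")
    TRUE
  })

#' Construct a ProbabilitySample
#'
#' @param probs numeric matrix (`T` passes x `n` instances) or a numeric
#'   vector, interpreted as the pass series of a single instance.
#' @return a [ProbabilitySample-class].
#' @examples
#' ps <- probabilitySample(rbind(c(0.2, 0.9), c(0.4, 0.8), c(0.6, 1.0)))
#' predictiveMean(ps)
#' @export
probabilitySample <- function(probs) {
  if (is.vector(probs)) probs <- matrix(probs, ncol = 1L)
  new("ProbabilitySample", probs = probs)
}

#' @describeIn ProbabilitySample number of stochastic passes `T`
#' @param x,object a `ProbabilitySample`
#' @export
nPasses <- function(x) nrow(x@probs)

#' @describeIn ProbabilitySample number of instances `n`
#' @export
nInstances <- function(x) ncol(x@probs)

#' @describeIn ProbabilitySample the raw `T x n` probability matrix
#' @export
probs <- function(x) x@probs

setMethod("show", "ProbabilitySample", function(object) {
  cat("ProbabilitySample:", nPasses(object), "passes x",
      nInstances(object), "instances\n")
  mu <- colMeans(object@probs)
  cat("  predictive mean range: [", sprintf("%.3f", min(mu)), ", ",
      sprintf("%.3f", max(mu)), "]\n", sep = "")
})

#' PredictiveSummary: per-instance uncertainty summary
#'
#' Per-instance predictive mean, predictive entropy (nats), normalised
#' entropy, hard label and certainty flag, as produced by
#' [summarizePredictions()]. For an OvA binary task the entropy is that of
#' the two-point distribution (mu, 1 - mu) and the normaliser is log(2), so
#' `entropyNorm` is scale-free in [0, 1] whatever the class count.
#'
#' @slot muPred numeric, predictive mean probability per instance.
#' @slot entropy numeric, predictive entropy in nats, in [0, log C].
#' @slot entropyNorm numeric, entropy / log(C), in [0, 1].
#' @slot predictedLabel integer, 1 iff `muPred >= 0.5`.
#' @slot certain logical, TRUE iff `entropyNorm <= threshold`.
#' @slot threshold numeric scalar used for the certainty partition.
#' @export
setClass("PredictiveSummary",
  representation(muPred = "numeric", entropy = "numeric",
                 entropyNorm = "numeric", predictedLabel = "integer",
                 certain = "logical", threshold = "numeric"),
  validity = function(object) {
    n <- length(object@muPred)
    if (any(lengths(list(object@entropy, object@entropyNorm,
                         object@predictedLabel, object@certain)) != n))
      return("all per-instance slots must have equal length")
    if (any(object@muPred < 0 | object@muPred > 1)) return("muPred outside [0, 1]")
    if (any(object@entropy < -1e-12)) return("negative entropy")
    if (any(object@entropyNorm < -1e-12 | object@entropyNorm > 1 + 1e-12))
      return("entropyNorm outside [0, 1]")
    if (!identical(object@predictedLabel,
                   as.integer(object@muPred >= 0.5)))
      return("predictedLabel must be 1 iff muPred >= 0.5")
    TRUE
  })

setMethod("show", "PredictiveSummary", function(object) {
  n <- length(object@muPred)
  cat("PredictiveSummary:", n, "instances, threshold",
      object@threshold, "\n")
  cat("  certain:", sum(object@certain), "/", n, "\n")
  cat("  mean entropy (norm):", sprintf("%.4f", mean(object@entropyNorm)), "\n")
})

#' @describeIn PredictiveSummary per-instance predictive mean
#' @param x a `PredictiveSummary`
#' @export
muPred <- function(x) x@muPred

#' @describeIn PredictiveSummary per-instance normalised predictive entropy
#' @export
entropyNorm <- function(x) x@entropyNorm

#' @describeIn PredictiveSummary per-instance hard labels (0/1)
#' @export
predictedLabel <- function(x) x@predictedLabel

#' @describeIn PredictiveSummary per-instance certainty flags
#' @export
isCertain <- function(x) x@certain

#' UncertaintyConfusionMatrix: correctness x certainty counts
#'
#' The 2x2 cross of prediction correctness and certainty: TC (correct and
#' certain), TU (incorrect and uncertain) — the desirable diagonal — plus FC
#' (incorrect but certain, the dangerous cell) and FU (correct but
#' uncertain). Feeds [uncertaintyMetrics()].
#'
#' @slot TC,TU,FC,FU non-negative integer counts; they sum to `n`.
#' @seealso [uncertaintyConfusion()], [uncertaintyMetrics()]
#' @export
setClass("UncertaintyConfusionMatrix",
  representation(TC = "integer", TU = "integer", FC = "integer",
                 FU = "integer"),
  validity = function(object) {
    v <- c(object@TC, object@TU, object@FC, object@FU)
    if (length(v) != 4L || anyNA(v)) return("TC, TU, FC, FU must be scalars")
    if (any(v < 0L)) return("counts must be non-negative")
    TRUE
  })

setMethod("show", "UncertaintyConfusionMatrix", function(object) {
  m <- matrix(c(object@TC, object@FC, object@FU, object@TU), 2, 2,
              dimnames = list(c("certain", "uncertain"),
                              c("correct", "incorrect")))
  cat("UncertaintyConfusionMatrix (n = ",
      object@TC + object@TU + object@FC + object@FU, ")\n", sep = "")
  print(m)
})

#' BinaryConfusionMatrix: TP/TN/FP/FN counts
#'
#' @slot TP,TN,FP,FN non-negative integer counts; they sum to `n`.
#' @seealso [binaryConfusion()], [traditionalMetrics()]
#' @export
setClass("BinaryConfusionMatrix",
  representation(TP = "integer", TN = "integer", FP = "integer",
                 FN = "integer"),
  validity = function(object) {
    v <- c(object@TP, object@TN, object@FP, object@FN)
    if (length(v) != 4L || anyNA(v)) return("TP, TN, FP, FN must be scalars")
    if (any(v < 0L)) return("counts must be non-negative")
    TRUE
  })

setMethod("show", "BinaryConfusionMatrix", function(object) {
  m <- matrix(c(object@TP, object@FN, object@FP, object@TN), 2, 2,
              dimnames = list(c("pred 1", "pred 0"), c("truth 1", "truth 0")))
  cat("BinaryConfusionMatrix (n = ",
      object@TP + object@TN + object@FP + object@FN, ")\n", sep = "")
  print(m)
})

#' LabeledDataset: feature matrix with integer class labels
#'
#' Instances in rows, features in columns, labels in `{0, ..., C-1}`. This is
#' the exchange object between the synthetic generator, the rebalancer, the
#' One-vs-All binarizer and the samplers.
#'
#' @slot features numeric matrix, `n x d`.
#' @slot labels integer vector of length `n`, values in `0:(C-1)`.
#' @slot nClasses integer, the class count `C`.
#' @seealso [labeledDataset()], [makeFeatures()], [oversampleBalance()],
#'   [binarize()]
#' @export
setClass("LabeledDataset",
  representation(features = "matrix", labels = "integer",
                 nClasses = "integer"),
  validity = function(object) {
    if (nrow(object@features) != length(object@labels))
      return("one label per feature row required")
    if (anyNA(object@features) || any(!is.finite(object@features)))
      return("features must be finite")
    if (length(object@nClasses) != 1L || object@nClasses < 1L)
      return("nClasses must be a positive scalar")
    if (any(object@labels < 0L | object@labels >= object@nClasses))
      return("labels must lie in 0:(nClasses - 1)")
    TRUE
  })

#' Construct a LabeledDataset
#'
#' @param features numeric matrix, instances in rows.
#' @param labels integer-like vector of class labels in `0:(C-1)`.
#' @param nClasses class count; defaults to `max(labels) + 1`.
#' @return a [LabeledDataset-class].
#' @export
labeledDataset <- function(features, labels, nClasses = NULL) {
  labels <- as.integer(labels)
  if (is.null(nClasses)) nClasses <- max(labels) + 1L
  new("LabeledDataset", features = as.matrix(features), labels = labels,
      nClasses = as.integer(nClasses))
}

#' @describeIn LabeledDataset the `n x d` feature matrix
#' @param x,object a `LabeledDataset`
#' @export
features <- function(x) x@features

#' @describeIn LabeledDataset the integer label vector
#' @export
labels0 <- function(x) x@labels

#' @describeIn LabeledDataset per-class instance counts (named by class)
#' @export
classCounts <- function(x) {
  tabulate(x@labels + 1L, nbins = x@nClasses) |>
    stats::setNames(as.character(seq_len(x@nClasses) - 1L))
}

setMethod("show", "LabeledDataset", function(object) {
  cat("LabeledDataset:", nrow(object@features), "instances x",
      ncol(object@features), "features,", object@nClasses, "classes\n")
  cat("  class counts:",
      paste(names(classCounts(object)), classCounts(object),
            sep = "=", collapse = ", "), "\n")
})

#' StochasticPredictor: virtual parent of all reference predictors
#'
#' The contract every predictor honours: [sampleProbs()] yields a
#' [ProbabilitySample-class] reproducibly under a fixed seed, and
#' [paramCount()] reports trainable parameters.
#'
#' @export
setClass("StochasticPredictor", representation("VIRTUAL"))

#' DropoutNet: feed-forward network with dropout layers
#'
#' A fully connected rectifier network with a dropout layer after each hidden
#' layer and a single logistic output unit. With dropout masks kept active at
#' inference, repeated forward passes realise Monte Carlo dropout sampling.
#'
#' @slot W list of weight matrices (fan-in x fan-out per layer).
#' @slot b list of bias vectors.
#' @slot dropout numeric dropout rate applied after each hidden layer.
#' @slot spec the [referenceNetSpec()] list the net was built from.
#' @seealso [buildReferenceNet()], [trainPredictor()], [mcDropoutSample()]
#' @export
setClass("DropoutNet", contains = "StochasticPredictor",
  representation(W = "list", b = "list", dropout = "numeric", spec = "list"))

#' BayesNet: mean-field Gaussian weight-posterior network
#'
#' Same layer stack as [DropoutNet-class] but every weight and bias carries an
#' independent Gaussian posterior (mean + softplus-parameterised spread).
#' Each stochastic pass draws one full weight realisation; zero posterior
#' spread collapses to a deterministic network.
#'
#' @slot muW,muB lists of posterior means (weights, biases).
#' @slot rhoW,rhoB lists of posterior spread parameters; the standard
#'   deviation is `log(1 + exp(rho))`.
#' @slot spec the [referenceNetSpec()] list the net was built from.
#' @seealso [buildBayesNet()], [trainPredictor()], [bayesSample()]
#' @export
setClass("BayesNet", contains = "StochasticPredictor",
  representation(muW = "list", muB = "list", rhoW = "list", rhoB = "list",
                 spec = "list"))

#' DeepEnsemble: a collection of member predictors
#'
#' Members are independently initialised (and independently data-shuffled)
#' networks; one deterministic pass per member realises the deep-ensemble
#' predictive distribution, while `passes > 1` on dropout members realises
#' ensemble Monte Carlo dropout.
#'
#' @slot members list of [StochasticPredictor-class] objects.
#' @seealso [trainEnsemble()], [ensembleSample()], [emcSample()]
#' @export
setClass("DeepEnsemble", contains = "StochasticPredictor",
  representation(members = "list"),
  validity = function(object) {
    if (length(object@members) < 1L) return("ensemble needs >= 1 member")
    ok <- vapply(object@members, is, logical(1), class2 = "StochasticPredictor")
    if (!all(ok)) return("all members must be StochasticPredictors")
    TRUE
  })

#' @describeIn DeepEnsemble list of member predictors
#' @param x a `DeepEnsemble`
#' @export
members <- function(x) x@members

setMethod("show", "DropoutNet", function(object) {
  cat("DropoutNet:", paste(object@spec$inputDim), "->",
      paste(object@spec$hidden, collapse = " -> "), "-> 1 (logistic)\n")
  cat("  dropout:", object@dropout, " parameters:", paramCount(object), "\n")
})

setMethod("show", "BayesNet", function(object) {
  cat("BayesNet (mean-field Gaussian):", paste(object@spec$inputDim), "->",
      paste(object@spec$hidden, collapse = " -> "), "-> 1 (logistic)\n")
  cat("  weight-mean parameters:", paramCount(object), "\n")
})

setMethod("show", "DeepEnsemble", function(object) {
  cat("DeepEnsemble:", length(object@members), "members,",
      paramCount(object), "total parameters\n")
})
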