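#' @import methods
#' @importFrom stats rnorm runif rbinom sd
NULL

#' Number of trainable parameters of a predictor
#'
#' For layered networks this is the closed-form sum over dense layers of
#' \eqn{(\mathrm{fan~in}+1)\times\mathrm{fan~out}}; for an ensemble it is the
#' member count times the single-member total. For a Gaussian-posterior
#' network the count refers to the weight means (the posterior carries an
#' equal number of spread parameters on top).
#'
#' @param object a [StochasticPredictor-class] (or subclass).
#' @return integer scalar.
#' @examples
#' net <- buildReferenceNet(referenceNetSpec(), seed = 1L)
#' paramCount(net)  # 29697
#' @export
setGeneric("paramCount", function(object) standardGeneric("paramCount"))

#' Draw stochastic forward-pass probability samples
#'
#' Produces a [ProbabilitySample-class]: a `T x n` matrix of positive-class
#' probabilities, one row per stochastic realisation of the predictor. How
#' stochasticity enters depends on the predictor: dropout masks for
#' [DropoutNet-class], posterior weight draws for [BayesNet-class], member
#' identity (with dropout off) for [DeepEnsemble-class]. Repeated calls with
#' the same `seed` are bit-identical.
#'
#' @param object a predictor.
#' @param features numeric matrix, instances in rows.
#' @param passes integer, number of stochastic passes per stochastic member
#'   (ignored by plain ensembles, which contribute one deterministic pass per
#'   member).
#' @param seed integer seed controlling the stochastic draws.
#' @return a [ProbabilitySample-class].
#' @export
setGeneric("sampleProbs", function(object, features, passes = 50L, seed = 1L)
  standardGeneric("sampleProbs"))

#' Deterministic forward pass (stochasticity switched off)
#'
#' Dropout masks are disabled and Gaussian posteriors collapse to their means;
#' ensembles average their members' deterministic outputs.
#'
#' @param object a predictor.
#' @param features numeric matrix, instances in rows.
#' @return numeric vector of positive-class probabilities, one per instance.
#' @export
setGeneric("predictProb", function(object, features)
  standardGeneric("predictProb"))
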