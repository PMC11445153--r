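## User-facing stochastic samplers: MC dropout, deep ensembles, ensemble MC
## dropout, and the sampleProbs methods tying them to the predictor classes.

#' Monte Carlo dropout sampling
#'
#' Keeps the dropout layers active at inference and performs `passes`
#' independent dropout-masked forward passes; each pass is one Monte Carlo
#' draw from the approximate posterior predictive distribution. With dropout
#' rate 0 all passes coincide with the deterministic forward pass.
#'
#' @param net a [DropoutNet-class].
#' @param features numeric matrix, instances in rows.
#' @param passes number of stochastic passes `T`.
#' @param seed integer RNG seed; fixed seed gives bit-identical samples.
#' @return a [ProbabilitySample-class] with `passes` rows.
#' @export
mcDropoutSample <- function(net, features, passes = 50L, seed = 1L) {
  stopifnot(is(net, "DropoutNet"))
  if (passes < 1L) stop("invalid parameter: passes must be >= 1")
  features <- as.matrix(features)
  set.seed(seed)
  P <- matrix(NA_real_, passes, nrow(features))
  for (t in seq_len(passes))
    P[t, ] <- netForward(net@W, net@b, features, net@dropout,
                         stochastic = TRUE)$p
  probabilitySample(P)
}

#' Deep-ensemble sampling (one deterministic pass per member)
#'
#' Row `t` of the result is member `t`'s deterministic prediction (dropout
#' off, posteriors collapsed to their means); the column means realise the
#' ensemble predictive mean.
#'
#' @param ensemble a [DeepEnsemble-class].
#' @param features numeric matrix, instances in rows.
#' @return a [ProbabilitySample-class] with one row per member.
#' @export
ensembleSample <- function(ensemble, features) {
  stopifnot(is(ensemble, "DeepEnsemble"))
  P <- do.call(rbind, lapply(ensemble@members, predictProb,
                             features = features))
  probabilitySample(P)
}

#' Ensemble Monte Carlo dropout sampling
#'
#' Concatenates each member's MC-dropout passes into one pooled sample of
#' `M x passesPerMember` rows; the pooled mean is the ensemble-MC predictive
#' mean. With one member this reduces exactly to [mcDropoutSample()]; with
#' dropout rate 0 and one pass per member it reduces exactly to
#' [ensembleSample()].
#'
#' @param ensemble a [DeepEnsemble-class] of [DropoutNet-class] (or
#'   [BayesNet-class]) members.
#' @param features numeric matrix, instances in rows.
#' @param passesPerMember stochastic passes per member.
#' @param seed integer RNG seed; member draws use seeds derived from it.
#' @return a [ProbabilitySample-class].
#' @export
emcSample <- function(ensemble, features, passesPerMember = 10L, seed = 1L) {
  stopifnot(is(ensemble, "DeepEnsemble"))
  if (passesPerMember < 1L)
    stop("invalid parameter: passesPerMember must be >= 1")
  ## consecutive member seeds so a single-member ensemble reduces exactly
  ## to mcDropoutSample / bayesSample under the same seed
  memberSeeds <- seed + seq_along(ensemble@members) - 1L
  rows <- mapply(function(m, s) {
    probs(sampleProbs(m, features, passes = passesPerMember, seed = s))
  }, ensemble@members, memberSeeds, SIMPLIFY = FALSE)
  probabilitySample(do.call(rbind, rows))
}

## independent per-member seeds from one master seed, kept below 2^31
deriveSeeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Train a deep ensemble of independently initialised members
#'
#' Member diversity comes from distinct initialisation seeds and distinct
#' data-shuffle seeds derived from `seed` (no bagging).
#'
#' @param spec a [referenceNetSpec()].
#' @param features,labels training data (labels 0/1).
#' @param cfg a [trainConfig()]; its seed is superseded by per-member seeds.
#' @param nMembers ensemble size `M` (default 5).
#' @param seed master seed.
#' @param bayes if TRUE, members are [BayesNet-class] (an ensemble Bayesian
#'   network); otherwise dropout networks.
#' @return a [DeepEnsemble-class] of trained members.
#' @export
trainEnsemble <- function(spec, features, labels, cfg = trainConfig(),
                          nMembers = 5L, seed = 1L, bayes = FALSE) {
  if (nMembers < 1L) stop("invalid spec: ensemble needs >= 1 member")
  seeds <- deriveSeeds(seed, 2L * nMembers)
  members <- vector("list", nMembers)
  for (i in seq_len(nMembers)) {
    net <- if (bayes) buildBayesNet(spec, seed = seeds[i])
           else buildReferenceNet(spec, seed = seeds[i])
    mcfg <- cfg; mcfg$seed <- seeds[nMembers + i]
    members[[i]] <- trainPredictor(net, features, labels, mcfg)$predictor
  }
  new("DeepEnsemble", members = members)
}

#' @rdname sampleProbs
#' @export
setMethod("sampleProbs", "DropoutNet", function(object, features, passes,
                                                seed) {
  mcDropoutSample(object, features, passes, seed)
})

#' @rdname sampleProbs
#' @export
setMethod("sampleProbs", "BayesNet", function(object, features, passes,
                                              seed) {
  bayesSample(object, features, passes, seed)
})

#' @rdname sampleProbs
#' @export
setMethod("sampleProbs", "DeepEnsemble", function(object, features, passes,
                                                  seed) {
  emcSample(object, features, passesPerMember = passes, seed = seed)
})
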