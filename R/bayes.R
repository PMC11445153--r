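## Mean-field Gaussian weight-posterior network ("Bayes by backprop" style):
## every weight/bias has an independent N(mu, sigma^2) posterior with
## sigma = softplus(rho); training minimises minibatch BCE plus the KL to a
## standard-normal prior, reweighted by 1 / number of minibatches; each
## stochastic pass at inference draws one full weight realisation.

softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)

#' Build a mean-field Gaussian Bayesian network
#'
#' Posterior means use the same variance-scaled initialisation as
#' [buildReferenceNet()]; posterior spreads start small (rho = -5,
#' sigma about 0.0067) so early training is near-deterministic.
#'
#' @param spec a [referenceNetSpec()] (the dropout rate is ignored: the
#'   stochasticity of this predictor is the weight posterior).
#' @param seed integer RNG seed for the initial means.
#' @return a [BayesNet-class].
#' @export
buildBayesNet <- function(spec = referenceNetSpec(), seed = 1L) {
  stopifnot(inherits(spec, "referenceNetSpec"))
  det <- buildReferenceNet(spec, seed)
  new("BayesNet", muW = det@W, muB = det@b,
      rhoW = lapply(det@W, function(w) w * 0 - 5),
      rhoB = lapply(det@b, function(v) v * 0 - 5),
      spec = unclass(spec))
}

#' @rdname paramCount
#' @export
setMethod("paramCount", "BayesNet", function(object) {
  sum(vapply(object@muW, function(w) (nrow(w) + 1L) * ncol(w), numeric(1)))
})

## draw one full weight realisation W = mu + softplus(rho) * eps
bayesDraw <- function(net) {
  drawOne <- function(mu, rho) {
    eps <- array(rnorm(length(mu)), dim = dim(mu) %||% length(mu))
    list(value = mu + softplus(rho) * eps, eps = eps)
  }
  W <- eW <- vector("list", length(net@muW))
  b <- eB <- vector("list", length(net@muB))
  for (l in seq_along(net@muW)) {
    dw <- drawOne(net@muW[[l]], net@rhoW[[l]])
    W[[l]] <- dw$value; eW[[l]] <- dw$eps
    db <- drawOne(net@muB[[l]], net@rhoB[[l]])
    b[[l]] <- as.numeric(db$value); eB[[l]] <- db$eps
  }
  list(W = W, b = b, eW = eW, eB = eB)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

checkFiniteVariational <- function(net) {
  ok <- all(vapply(c(net@muW, net@muB, net@rhoW, net@rhoB),
                   function(p) all(is.finite(p)), logical(1)))
  if (!ok) stop("invalid state: non-finite variational parameters")
}

trainBayesNet <- function(net, X, y, cfg) {
  checkFiniteVariational(net)
  set.seed(cfg$seed)
  n <- nrow(X)
  L <- length(net@muW)
  mu <- c(net@muW, net@muB)
  rho <- c(net@rhoW, net@rhoB)
  stMu <- adamInit(mu); stRho <- adamInit(rho)
  nBatches <- length(seq(1L, n, by = cfg$batchSize))
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    for (s in seq(1L, n, by = cfg$batchSize)) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
      nb <- length(idx)
      ## one posterior draw per minibatch (reparameterisation trick)
      net@muW <- mu[seq_len(L)]; net@muB <- mu[L + seq_len(L)]
      net@rhoW <- rho[seq_len(L)]; net@rhoB <- rho[L + seq_len(L)]
      draw <- bayesDraw(net)
      fwd <- netForward(draw$W, draw$b, X[idx, , drop = FALSE],
                        dropout = 0, stochastic = FALSE)
      g <- netBackward(draw$W, fwd, y[idx])
      dTheta <- c(g$dW, g$db)          # gradient w.r.t. realised weights
      eps <- c(draw$eW, draw$eB)
      ## KL(q || N(0,1)) per parameter, reweighted per minibatch and per
      ## instance so it lives on the same mean-loss scale as the BCE
      klw <- 1 / (nBatches * nb)
      gMu <- gRho <- vector("list", 2L * L)
      for (i in seq_along(mu)) {
        sdev <- softplus(rho[[i]])
        dsd <- sigmoid(rho[[i]])       # d softplus / d rho
        gMu[[i]] <- dTheta[[i]] + klw * mu[[i]]
        gRho[[i]] <- dTheta[[i]] * eps[[i]] * dsd +
          klw * (sdev - 1 / sdev) * dsd
      }
      updMu <- adamStep(mu, gMu, stMu, cfg$learningRate)
      mu <- updMu$params; stMu <- updMu$state
      updRho <- adamStep(rho, gRho, stRho, cfg$learningRate)
      rho <- updRho$params; stRho <- updRho$state
      epochLoss <- epochLoss + bceLoss(fwd$p, y[idx]) * nb
    }
    history[epoch] <- epochLoss / n
  }
  net@muW <- mu[seq_len(L)]
  net@muB <- lapply(mu[L + seq_len(L)], as.numeric)
  net@rhoW <- rho[seq_len(L)]
  net@rhoB <- lapply(rho[L + seq_len(L)], as.numeric)
  list(predictor = net, lossHistory = history)
}

#' Rescale the posterior spread of a BayesNet
#'
#' Multiplies every posterior standard deviation by `factor` (0 collapses
#' the posterior to its mean, making the predictor deterministic). Useful
#' for probing how predictive entropy responds to epistemic spread.
#'
#' @param net a [BayesNet-class].
#' @param factor non-negative scalar.
#' @return the rescaled [BayesNet-class].
#' @export
scalePosterior <- function(net, factor) {
  stopifnot(is(net, "BayesNet"), factor >= 0)
  resc <- function(rho) {
    s <- softplus(rho) * factor
    ifelse(s <= 0, -Inf, log(expm1(pmin(s, 30))) + pmax(s - 30, 0))
  }
  net@rhoW <- lapply(net@rhoW, resc)
  net@rhoB <- lapply(net@rhoB, resc)
  net
}

#' Draw posterior-predictive samples from a Bayesian network
#'
#' Each pass draws one full weight realisation from the mean-field Gaussian
#' posterior and performs a deterministic forward pass. Zero posterior
#' spread makes every pass identical.
#'
#' @param net a [BayesNet-class].
#' @param features numeric matrix, instances in rows.
#' @param passes number of posterior draws `T`.
#' @param seed integer RNG seed.
#' @return a [ProbabilitySample-class].
#' @export
bayesSample <- function(net, features, passes = 50L, seed = 1L) {
  checkFiniteVariational0(net)
  if (passes < 1L) stop("invalid parameter: passes must be >= 1")
  features <- as.matrix(features)
  set.seed(seed)
  P <- matrix(NA_real_, passes, nrow(features))
  for (t in seq_len(passes)) {
    draw <- bayesDraw(net)
    P[t, ] <- netForward(draw$W, draw$b, features, dropout = 0,
                         stochastic = FALSE)$p
  }
  probabilitySample(P)
}

## -Inf rho encodes an exactly-zero spread (see scalePosterior); allow it
checkFiniteVariational0 <- function(net) {
  ok <- all(vapply(c(net@muW, net@muB), function(p) all(is.finite(p)),
                   logical(1))) &&
    all(vapply(c(net@rhoW, net@rhoB),
               function(p) all(is.finite(p) | p == -Inf), logical(1)))
  if (!ok) stop("invalid state: non-finite variational parameters")
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "BayesNet", function(object, features) {
  netForward(object@muW, object@muB, as.matrix(features), dropout = 0,
             stochastic = FALSE)$p
})
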