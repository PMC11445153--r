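## Dropout feed-forward network internals: initialisation, forward/backward
## passes, Adam optimisation. All randomness is drawn from R's RNG so a
## single set.seed() makes training and sampling bit-reproducible.

#' Reference network specification
#'
#' The default stack is a 150-input fully connected rectifier network with
#' hidden widths 128, 64 and 32, a dropout layer (rate 0.5) after each
#' hidden layer and a single logistic output unit; its parameter total is
#' 29,697 (per layer: 19,328 / 8,256 / 2,080 / 33).
#'
#' @param inputDim number of input features (default 150).
#' @param hidden integer vector of hidden-layer widths; an empty vector
#'   gives a bare logistic unit.
#' @param dropout dropout rate applied after each hidden layer.
#' @return a list with class `"referenceNetSpec"`.
#' @export
referenceNetSpec <- function(inputDim = 150L, hidden = c(128L, 64L, 32L),
                             dropout = 0.5) {
  if (inputDim < 1L || any(hidden < 1L))
    stop("invalid spec: layer widths must be positive")
  if (dropout < 0 || dropout >= 1)
    stop("invalid spec: dropout rate must be in [0, 1)")
  structure(list(inputDim = as.integer(inputDim),
                 hidden = as.integer(hidden), dropout = dropout),
            class = "referenceNetSpec")
}

## closed form: sum over dense layers of (fan_in + 1) * fan_out
specParamCount <- function(spec) {
  dims <- c(spec$inputDim, spec$hidden, 1L)
  sum((dims[-length(dims)] + 1L) * dims[-1L])
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.001, 15 epochs, batch size 64, binary cross-entropy loss.
#'
#' @param learningRate Adam step size.
#' @param epochs number of passes over the training data (0 = no training).
#' @param batchSize minibatch size.
#' @param seed RNG seed controlling shuffling, dropout masks and (for
#'   Bayesian nets) weight draws during training.
#' @return a list with class `"trainConfig"`.
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 15L, batchSize = 64L,
                        seed = 1L) {
  if (learningRate <= 0 || epochs < 0 || batchSize < 1L)
    stop("invalid config: learningRate, epochs, batchSize must be positive")
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "trainConfig")
}

#' Build a dropout reference network
#'
#' Weights use variance-scaled Gaussian initialisation (scale 2/fan-in for
#' rectifier layers, 1/fan-in for the logistic output); biases start at 0.
#'
#' @param spec a [referenceNetSpec()].
#' @param seed integer RNG seed for the initial weights.
#' @return a [DropoutNet-class].
#' @examples
#' net <- buildReferenceNet(referenceNetSpec(), seed = 7L)
#' paramCount(net)
#' @export
buildReferenceNet <- function(spec = referenceNetSpec(), seed = 1L) {
  stopifnot(inherits(spec, "referenceNetSpec"))
  set.seed(seed)
  dims <- c(spec$inputDim, spec$hidden, 1L)
  L <- length(dims) - 1L
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    scale <- if (l < L) sqrt(2 / dims[l]) else sqrt(1 / dims[l])
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = scale),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  new("DropoutNet", W = W, b = b, dropout = spec$dropout, spec = unclass(spec))
}

#' @rdname paramCount
#' @export
setMethod("paramCount", "DropoutNet", function(object) {
  sum(vapply(object@W, function(w) (nrow(w) + 1L) * ncol(w), numeric(1)))
})

#' @rdname paramCount
#' @export
setMethod("paramCount", "DeepEnsemble", function(object) {
  sum(vapply(object@members, paramCount, numeric(1)))
})

sigmoid <- function(z) 1 / (1 + exp(-z))

## forward pass caching pre-activations and dropout masks (for backprop).
## stochastic = TRUE keeps dropout masks active (training and MC inference).
netForward <- function(W, b, X, dropout, stochastic) {
  L <- length(W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  mask <- vector("list", L - 1L)
  A[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
    A[[l + 1L]] <- pmax(Z[[l]], 0)
    if (stochastic && dropout > 0) {
      keep <- 1 - dropout
      m <- matrix(rbinom(length(Z[[l]]), 1L, keep) / keep,
                  nrow(Z[[l]]), ncol(Z[[l]]))
      mask[[l]] <- m
      A[[l + 1L]] <- A[[l + 1L]] * m
    }
  }
  Z[[L]] <- sweep(A[[L]] %*% W[[L]], 2L, b[[L]], "+")
  p <- sigmoid(Z[[L]])
  list(A = A, Z = Z, mask = mask, p = as.numeric(p))
}

## mean binary cross-entropy with clipping
bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## gradients of mean BCE w.r.t. W and b, given a forward cache
netBackward <- function(W, fwd, y) {
  L <- length(W)
  nb <- length(y)
  dW <- db <- vector("list", L)
  dZ <- matrix((fwd$p - y) / nb, nb, 1L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fwd$A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(W[[l]])
      if (!is.null(fwd$mask[[l - 1L]])) dA <- dA * fwd$mask[[l - 1L]]
      dZ <- dA * (fwd$Z[[l - 1L]] > 0)
    }
  }
  list(dW = dW, db = db)
}

## Adam state as flat lists parallel to the parameter lists
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

trainDropoutNet <- function(net, X, y, cfg) {
  set.seed(cfg$seed)
  n <- nrow(X)
  params <- c(net@W, net@b)
  L <- length(net@W)
  state <- adamInit(params)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batchSize)
    epochLoss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
      Wl <- params[seq_len(L)]; bl <- params[L + seq_len(L)]
      fwd <- netForward(Wl, bl, X[idx, , drop = FALSE], net@dropout,
                        stochastic = TRUE)
      g <- netBackward(Wl, fwd, y[idx])
      upd <- adamStep(params, c(g$dW, g$db), state, cfg$learningRate)
      params <- upd$params; state <- upd$state
      epochLoss <- epochLoss + bceLoss(fwd$p, y[idx]) * length(idx)
    }
    history[epoch] <- epochLoss / n
  }
  net@W <- params[seq_len(L)]
  net@b <- lapply(params[L + seq_len(L)], as.numeric)
  list(predictor = net, lossHistory = history)
}

#' Train a predictor with minibatch Adam and binary cross-entropy
#'
#' Dropout networks train with dropout masks active; Gaussian-posterior
#' networks train variationally (one posterior weight draw per minibatch,
#' standard-normal prior, KL penalty weighted by 1/number-of-batches). A
#' non-decreasing or non-finite loss trajectory is flagged with a warning,
#' never an error.
#'
#' @param predictor a [DropoutNet-class] or [BayesNet-class].
#' @param features numeric training matrix, instances in rows.
#' @param labels 0/1 vector.
#' @param cfg a [trainConfig()].
#' @return list with `predictor` (trained) and `lossHistory` (length =
#'   epochs; empty when `epochs = 0`, in which case the predictor is
#'   returned unchanged).
#' @export
trainPredictor <- function(predictor, features, labels,
                           cfg = trainConfig()) {
  features <- as.matrix(features)
  if (anyNA(features) || any(!is.finite(features)))
    stop("invalid input: features must be finite")
  if (!all(labels %in% c(0, 1)))
    stop("invalid input: labels must be binary 0/1")
  if (nrow(features) != length(labels))
    stop("invalid input: one label per instance required")
  if (cfg$epochs == 0L)
    return(list(predictor = predictor, lossHistory = numeric(0)))
  out <- if (is(predictor, "BayesNet")) {
    trainBayesNet(predictor, features, labels, cfg)
  } else if (is(predictor, "DropoutNet")) {
    trainDropoutNet(predictor, features, labels, cfg)
  } else stop("unsupported predictor class: ", class(predictor))
  if (any(!is.finite(out$lossHistory)) ||
      out$lossHistory[length(out$lossHistory)] > out$lossHistory[1L] * 2)
    warning("training loss diverged; predictor returned as-is")
  out
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "DropoutNet", function(object, features) {
  netForward(object@W, object@b, as.matrix(features), object@dropout,
             stochastic = FALSE)$p
})

#' @rdname predictProb
#' @export
setMethod("predictProb", "DeepEnsemble", function(object, features) {
  pm <- lapply(object@members, predictProb, features = features)
  rowMeans(do.call(cbind, pm))
})
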