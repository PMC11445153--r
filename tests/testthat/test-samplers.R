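test_that("parameter counts reproduce the closed form (fan_in + 1) x fan_out", {
  net <- buildReferenceNet(referenceNetSpec(), seed = 1L)
  perLayer <- vapply(net@W, function(w) (nrow(w) + 1L) * ncol(w), numeric(1))
  expect_equal(perLayer, c(19328, 8256, 2080, 33))
  expect_equal(paramCount(net), 29697)
  # bare logistic unit and a one-hidden-layer net
  expect_equal(paramCount(buildReferenceNet(
    referenceNetSpec(inputDim = 2L, hidden = integer(0)), 1L)), 3)
  expect_equal(paramCount(buildReferenceNet(
    referenceNetSpec(inputDim = 10L, hidden = 4L), 1L)), 49)
  # property: random specs agree with the closed-form sum
  set.seed(3)
  for (i in 1:10) {
    spec <- referenceNetSpec(inputDim = sample(1:40, 1),
                             hidden = sample(1:30, sample(1:4, 1)))
    dims <- c(spec$inputDim, spec$hidden, 1L)
    closed <- sum((dims[-length(dims)] + 1L) * dims[-1L])
    expect_equal(paramCount(buildReferenceNet(spec, seed = i)), closed)
  }
  expect_error(referenceNetSpec(hidden = c(12L, 0L)), "invalid spec")
})

test_that("a five-member ensemble carries five times the parameters", {
  ds <- tinyDataset(counts = c(20L, 20L), nFeatures = 150L)
  ens <- trainEnsemble(referenceNetSpec(), features(ds),
                       as.integer(labels0(ds) == 0L),
                       cfg = trainConfig(epochs = 0L), nMembers = 5L)
  expect_equal(paramCount(ens), 148485)
  expect_error(trainEnsemble(referenceNetSpec(), features(ds),
                             labels0(ds), nMembers = 0L), "invalid spec")
})

test_that("MC dropout is stochastic, seeded, and collapses at rate zero", {
  ds <- tinyDataset(counts = c(30L, 30L), separation = 2)
  y <- as.integer(labels0(ds) == 0L)
  net <- trainPredictor(buildReferenceNet(tinySpec(), 2L), features(ds), y,
                        tinyCfg())$predictor
  X <- features(ds)[1:5, ]
  # rate 0: all passes equal the deterministic pass
  net0 <- net; net0@dropout <- 0
  P0 <- probs(mcDropoutSample(net0, X, passes = 5L, seed = 4L))
  expect_equal(apply(P0, 2, stats::sd), rep(0, 5))
  expect_equal(P0[1, ], predictProb(net0, X))
  # determinism contract
  expect_identical(probs(mcDropoutSample(net, X, passes = 50L, seed = 9L)),
                   probs(mcDropoutSample(net, X, passes = 50L, seed = 9L)))
  expect_error(mcDropoutSample(net, X, passes = 0L), "invalid parameter")
  # with dropout active the passes spread, and the T = 200 mean sits within
  # 3 Monte Carlo standard errors of a T = 10,000 reference run
  x1 <- X[1, , drop = FALSE]
  small <- probs(mcDropoutSample(net, x1, passes = 200L, seed = 21L))
  expect_gt(stats::sd(small), 0)
  big <- probs(mcDropoutSample(net, x1, passes = 10000L, seed = 22L))
  se <- stats::sd(big) / sqrt(200)
  expect_lt(abs(mean(small) - mean(big)), 3 * se)
})

test_that("training reduces loss and fits separable blobs", {
  set.seed(31)
  n <- 120
  X <- rbind(matrix(rnorm(n, mean = -2), n / 2, 2),
             matrix(rnorm(n, mean = 2), n / 2, 2))
  y <- rep(c(0L, 1L), each = n / 2)
  net <- buildReferenceNet(referenceNetSpec(inputDim = 2L, hidden = c(8L, 4L),
                                            dropout = 0.1), seed = 5L)
  fit <- trainPredictor(net, X, y, trainConfig(epochs = 15L, batchSize = 8L,
                                               seed = 6L))
  expect_length(fit$lossHistory, 15L)
  expect_lt(fit$lossHistory[15L], fit$lossHistory[1L])
  acc <- mean(as.integer(predictProb(fit$predictor, X) >= 0.5) == y)
  expect_gte(acc, 0.95)
  # zero epochs: unchanged predictor, empty history
  un <- trainPredictor(net, X, y, trainConfig(epochs = 0L))
  expect_identical(un$predictor@W, net@W)
  expect_length(un$lossHistory, 0L)
  # constant labels: predictions converge toward the base rate (1)
  cl <- trainPredictor(net, X, rep(1L, n),
                       trainConfig(epochs = 15L, batchSize = 8L, seed = 2L))
  expect_gt(mean(predictProb(cl$predictor, X)), 0.9)
  expect_error(trainPredictor(net, X * NA, y, trainConfig()), "finite")
  expect_error(trainPredictor(net, X, y + 1L, trainConfig()), "binary")
})

test_that("ensemble sampling is one deterministic pass per member", {
  ds <- tinyDataset(counts = c(30L, 30L), separation = 2)
  y <- as.integer(labels0(ds) == 0L)
  X <- features(ds)[1:6, ]
  ens <- trainEnsemble(tinySpec(), features(ds), y, tinyCfg(),
                       nMembers = 5L, seed = 3L)
  P <- probs(ensembleSample(ens, X))
  expect_identical(dim(P), c(5L, 6L))
  # per-member loop oracle
  for (m in 1:5)
    expect_equal(P[m, ], predictProb(members(ens)[[m]], X))
  # identical members: zero across-member variance, pooled entropy equals
  # the single-member entropy
  same <- new("DeepEnsemble", members = rep(members(ens)[1], 3))
  Ps <- ensembleSample(same, X)
  expect_equal(apply(probs(Ps), 2, stats::sd), rep(0, 6))
  expect_equal(summarizePredictions(Ps)@entropy,
               binaryEntropyOracle(predictProb(members(ens)[[1]], X)))
  expect_error(new("DeepEnsemble", members = list()), ">= 1 member")
})

test_that("antagonistic members give mean 0.5 and maximal entropy", {
  # two bare logistic units with zero weights and biases at logit(0.2)/(0.8)
  mk <- function(p) {
    net <- buildReferenceNet(referenceNetSpec(inputDim = 3L,
                                              hidden = integer(0)), 1L)
    net@W[[1]][] <- 0; net@b[[1]] <- log(p / (1 - p))
    net
  }
  ens <- new("DeepEnsemble", members = list(mk(0.2), mk(0.8)))
  X <- matrix(rnorm(12), 4, 3)
  s <- summarizePredictions(ensembleSample(ens, X))
  expect_equal(muPred(s), rep(0.5, 4))
  expect_equal(entropyNorm(s), rep(1, 4))
})

test_that("ensemble MC dropout pools member passes and nests correctly", {
  ds <- tinyDataset(counts = c(30L, 30L), separation = 2)
  y <- as.integer(labels0(ds) == 0L)
  X <- features(ds)[1:4, ]
  ens <- trainEnsemble(tinySpec(), features(ds), y, tinyCfg(),
                       nMembers = 3L, seed = 8L)
  P <- probs(emcSample(ens, X, passesPerMember = 10L, seed = 17L))
  expect_identical(dim(P), c(30L, 4L))
  # nested-loop oracle: member m's block is its own MC sample
  for (m in 1:3) {
    block <- P[(10 * (m - 1) + 1):(10 * m), ]
    expect_identical(block, probs(mcDropoutSample(members(ens)[[m]], X,
                                                  10L, seed = 17L + m - 1L)))
  }
  # M = 1 reduces exactly to mcDropoutSample under the same seed
  one <- new("DeepEnsemble", members = members(ens)[1])
  expect_identical(probs(emcSample(one, X, 10L, seed = 5L)),
                   probs(mcDropoutSample(members(ens)[[1]], X, 10L, seed = 5L)))
  # dropout 0, one pass per member reduces exactly to ensembleSample
  ens0 <- new("DeepEnsemble", members = lapply(members(ens), function(m) {
    m@dropout <- 0; m
  }))
  expect_equal(probs(emcSample(ens0, X, 1L, seed = 2L)),
               probs(ensembleSample(ens0, X)))
})

test_that("Bayesian weight sampling is seeded and spread-sensitive", {
  ds <- tinyDataset(counts = c(40L, 40L), separation = 2)
  y <- as.integer(labels0(ds) == 0L)
  bn <- trainPredictor(buildBayesNet(tinySpec(), seed = 3L), features(ds), y,
                       tinyCfg(seed = 4L))$predictor
  X <- features(ds)[1:8, ]
  expect_identical(probs(bayesSample(bn, X, 20L, seed = 6L)),
                   probs(bayesSample(bn, X, 20L, seed = 6L)))
  # zero posterior spread: deterministic, equal to the mean forward pass
  frozen <- scalePosterior(bn, 0)
  Pf <- probs(bayesSample(frozen, X, 5L, seed = 1L))
  expect_equal(apply(Pf, 2, stats::sd), rep(0, 8))
  expect_equal(Pf[1, ], predictProb(bn, X))
  # widening the posterior never reduces mean predictive entropy
  set.seed(90)
  Xp <- matrix(rnorm(500 * 10), 500, 10)
  h1 <- mean(summarizePredictions(bayesSample(bn, Xp, 200L, seed = 2L))@entropy)
  h4 <- mean(summarizePredictions(
    bayesSample(scalePosterior(bn, 4), Xp, 200L, seed = 2L))@entropy)
  expect_gte(h4, h1)
  bad <- bn; bad@muW[[1]][1] <- NaN
  expect_error(bayesSample(bad, X, 5L), "invalid state")
})

test_that("sampleProbs dispatches to the technique-appropriate sampler", {
  ds <- tinyDataset(counts = c(20L, 20L), separation = 2)
  y <- as.integer(labels0(ds) == 0L)
  X <- features(ds)[1:3, ]
  net <- trainPredictor(buildReferenceNet(tinySpec(), 1L), features(ds), y,
                        tinyCfg())$predictor
  expect_identical(probs(sampleProbs(net, X, passes = 7L, seed = 3L)),
                   probs(mcDropoutSample(net, X, 7L, seed = 3L)))
  bn <- buildBayesNet(tinySpec(), seed = 2L)
  expect_identical(probs(sampleProbs(bn, X, passes = 4L, seed = 3L)),
                   probs(bayesSample(bn, X, 4L, seed = 3L)))
  ens <- new("DeepEnsemble", members = list(net, net))
  expect_identical(probs(sampleProbs(ens, X, passes = 3L, seed = 5L)),
                   probs(emcSample(ens, X, 3L, seed = 5L)))
})
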