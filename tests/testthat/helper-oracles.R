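# Independent brute-force oracles. These deliberately use plain loops and
# per-instance enumeration, not the vectorised code paths they check.

oracleMean <- function(P) {
  out <- numeric(ncol(P))
  for (i in seq_len(ncol(P))) {
    s <- 0
    for (t in seq_len(nrow(P))) s <- s + P[t, i]
    out[i] <- s / nrow(P)
  }
  out
}

oracleBrier <- function(mu, y) {
  s <- 0
  for (i in seq_along(mu)) s <- s + (mu[i] - y[i])^2
  s / length(mu)
}

# exhaustive positive x negative pair counting, ties count 1/2
oracleAUC <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# loop-based equal-width binning on confidence max(mu, 1 - mu)
oracleECE <- function(mu, y, M) {
  conf <- ifelse(mu >= 0.5, mu, 1 - mu)
  correct <- (mu >= 0.5) == (y == 1)
  edges <- seq(0, 1, length.out = M + 1)
  total <- 0
  for (m in seq_len(M)) {
    inB <- logical(length(mu))
    for (i in seq_along(mu)) {
      lo <- edges[m]; hi <- edges[m + 1]
      inB[i] <- if (m == 1) conf[i] >= lo && conf[i] <= hi
                else conf[i] > lo && conf[i] <= hi
    }
    if (any(inB))
      total <- total + sum(inB) / length(mu) *
        abs(mean(correct[inB]) - mean(conf[inB]))
  }
  total
}

# exhaustive per-instance 4-way tally of correctness x certainty
oracleUCM <- function(pred, truth, certain) {
  tc <- tu <- fc <- fu <- 0L
  for (i in seq_along(truth)) {
    if (pred[i] == truth[i] && certain[i]) tc <- tc + 1L
    else if (pred[i] != truth[i] && !certain[i]) tu <- tu + 1L
    else if (pred[i] != truth[i] && certain[i]) fc <- fc + 1L
    else fu <- fu + 1L
  }
  c(TC = tc, TU = tu, FC = fc, FU = fu)
}

ucmCounts <- function(cm) c(TC = cm@TC, TU = cm@TU, FC = cm@FC, FU = cm@FU)

# direct evaluation of the two-point Shannon entropy in nats
binaryEntropyOracle <- function(mu) {
  vapply(mu, function(m) {
    h <- 0
    for (p in c(m, 1 - m)) if (p > 0) h <- h - p * log(p)
    h
  }, numeric(1))
}

# a small overlapping 3-class dataset and cheap training config for
# pipeline-level tests
tinyDataset <- function(counts = c(60L, 50L, 40L), separation = 3,
                        nFeatures = 10L, seed = 7L) {
  makeFeatures(syntheticSpec(counts = counts, nFeatures = nFeatures,
                             separation = separation, seed = seed))
}

tinySpec <- function(d = 10L) referenceNetSpec(inputDim = d,
                                               hidden = c(16L, 8L))

# small batches and a faster step size keep the optimiser step count and
# movement adequate at tiny n
tinyCfg <- function(seed = 1L) trainConfig(learningRate = 0.005,
                                           epochs = 15L, batchSize = 16L,
                                           seed = seed)
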