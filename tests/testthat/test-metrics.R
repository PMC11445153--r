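test_that("predictive mean averages passes element-wise", {
  expect_equal(predictiveMean(probabilitySample(c(0.2, 0.4, 0.6))), 0.4)
  P <- matrix(0.37, 5, 3)
  expect_equal(predictiveMean(probabilitySample(P)), rep(0.37, 3))
  set.seed(101)
  P <- matrix(runif(10 * 50), 10, 50)
  expect_equal(predictiveMean(probabilitySample(P)), oracleMean(P),
               tolerance = 1e-12)
  expect_error(probabilitySample(matrix(numeric(0), 0, 0)), "at least one")
  expect_error(probabilitySample(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("predictive entropy follows the Shannon closed form", {
  expect_equal(predictiveEntropy(c(0.5, 0.5)), log(2))
  expect_equal(predictiveEntropy(c(1, 0)), 0)
  expect_equal(predictiveEntropy(c(0.9, 0.1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)))
  # bounded by log C, maximal at uniform
  expect_equal(predictiveEntropy(rep(1 / 4, 4)), log(4))
  expect_lt(predictiveEntropy(c(0.7, 0.1, 0.1, 0.1)), log(4))
  expect_error(predictiveEntropy(c(-0.1, 1.1)), "non-negative")
  expect_error(predictiveEntropy(c(0.5, 0.4)), "sum to 1")
})

test_that("certainty partition thresholds normalised entropy, ties certain", {
  expect_true(partitionCertainty(0, threshold = 0))
  expect_true(all(partitionCertainty(runif(20), threshold = 1)))
  expect_true(partitionCertainty(0.30, threshold = 0.30))  # boundary
  set.seed(42)
  hn <- runif(100)
  expect_identical(partitionCertainty(hn, 0.30),
                   vapply(hn, function(h) !(h > 0.30), logical(1)))
  expect_error(partitionCertainty(0.5, threshold = 1.5), "invalid parameter")
})

test_that("uncertainty confusion matrix tallies correctness x certainty", {
  cm <- uncertaintyConfusion(rep(1, 10), rep(1, 10), rep(TRUE, 10))
  expect_identical(ucmCounts(cm), c(TC = 10L, TU = 0L, FC = 0L, FU = 0L))
  cm <- uncertaintyConfusion(rep(1, 7), rep(0, 7), rep(FALSE, 7))
  expect_identical(ucmCounts(cm), c(TC = 0L, TU = 7L, FC = 0L, FU = 0L))
  set.seed(7)
  pred <- rbinom(200, 1, 0.5); truth <- rbinom(200, 1, 0.5)
  cert <- runif(200) < 0.6
  cm <- uncertaintyConfusion(pred, truth, cert)
  expect_identical(ucmCounts(cm), oracleUCM(pred, truth, cert))
  expect_identical(sum(ucmCounts(cm)), 200L)  # count conservation
  expect_error(uncertaintyConfusion(1, c(1, 0), TRUE), "equal length")
  expect_error(uncertaintyConfusion(2, 1, TRUE), "binary")
})

test_that("uncertainty metrics follow the TC/TU/FC/FU ratio definitions", {
  sym <- uncertaintyMetrics(new("UncertaintyConfusionMatrix",
                                TC = 25L, TU = 25L, FC = 25L, FU = 25L))
  expect_equal(sym[c("uAcc", "uSens", "uSpec", "uPrec")],
               list(uAcc = 0.5, uSens = 0.5, uSpec = 0.5, uPrec = 0.5))
  m <- uncertaintyMetrics(new("UncertaintyConfusionMatrix",
                              TC = 90L, TU = 5L, FC = 3L, FU = 2L))
  expect_equal(m$uAcc, 0.95)
  expect_equal(m$uSens, 5 / 8)
  expect_equal(m$uSpec, 90 / 92)
  expect_equal(m$uPrec, 5 / 7)
  expect_equal(m$uF1, 2 * (5 / 7) * (5 / 8) / (5 / 7 + 5 / 8))
  expect_false(m$degenerate)
  # all-certain-correct: 0/0 ratios return 0 and raise the flag
  z <- uncertaintyMetrics(new("UncertaintyConfusionMatrix",
                              TC = 10L, TU = 0L, FC = 0L, FU = 0L))
  expect_equal(z$uAcc, 1)
  expect_equal(z$uSens, 0)
  expect_equal(z$uSpec, 1)
  expect_true(z$degenerate)
  expect_error(new("UncertaintyConfusionMatrix",
                   TC = -1L, TU = 0L, FC = 0L, FU = 1L), "non-negative")
})

test_that("traditional metrics follow the TP/TN/FP/FN definitions", {
  perfect <- traditionalMetrics(new("BinaryConfusionMatrix",
                                    TP = 50L, TN = 50L, FP = 0L, FN = 0L))
  expect_equal(perfect[c("sensitivity", "specificity", "accuracy",
                         "precision", "f1")],
               list(sensitivity = 1, specificity = 1, accuracy = 1,
                    precision = 1, f1 = 1))
  worst <- traditionalMetrics(new("BinaryConfusionMatrix",
                                  TP = 0L, TN = 0L, FP = 50L, FN = 50L))
  expect_equal(worst$accuracy, 0)
  expect_true(worst$degenerate)
  m <- traditionalMetrics(new("BinaryConfusionMatrix",
                              TP = 40L, TN = 45L, FP = 5L, FN = 10L))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 8 / 9)
})

test_that("binary confusion matrix matches a direct cross-tabulation", {
  set.seed(11)
  pred <- rbinom(150, 1, 0.4); truth <- rbinom(150, 1, 0.5)
  cm <- binaryConfusion(pred, truth)
  expect_identical(cm@TP, sum(pred & truth))
  expect_identical(cm@TN, sum(!pred & !truth))
  expect_identical(cm@TP + cm@TN + cm@FP + cm@FN, 150L)
  expect_error(binaryConfusion(c(1, 0), 1), "length mismatch")
})

test_that("expected calibration error matches loop-based binning", {
  # confidence 1 everywhere: perfectly right then perfectly wrong
  expect_equal(ece(rep(1, 20), rep(1, 20))$ece, 0)
  expect_equal(ece(rep(1, 20), rep(0, 20))$ece, 1)
  set.seed(5)
  mu <- runif(500); y <- rbinom(500, 1, mu)
  got <- ece(mu, y, bins = 10L)
  expect_equal(got$ece, oracleECE(mu, y, 10), tolerance = 1e-12)
  expect_identical(sum(got$table$count), 500L)  # bins partition the sample
  # odd bin counts exercise the bin-edge conventions
  expect_equal(ece(mu, y, bins = 7L)$ece, oracleECE(mu, y, 7),
               tolerance = 1e-12)
  expect_error(ece(mu, y, bins = 0L), "invalid parameter")
})

test_that("Brier score is the mean squared probability error", {
  y <- c(0, 1, 1, 0)
  expect_equal(brierScore(y, y), 0)
  expect_equal(brierScore(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  set.seed(9)
  mu <- runif(100); y <- rbinom(100, 1, 0.5)
  expect_equal(brierScore(mu, y), oracleBrier(mu, y), tolerance = 1e-12)
  expect_error(brierScore(c(0.1, 0.2), 1), "length mismatch")
})

test_that("AUC-ROC equals exhaustive pair counting with ties at 1/2", {
  expect_equal(aucROC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucROC(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(13)
  scores <- round(runif(30), 1)  # rounding forces ties
  y <- rbinom(30, 1, 0.5)
  expect_equal(aucROC(scores, y), oracleAUC(scores, y), tolerance = 1e-12)
  expect_error(aucROC(runif(5), rep(1, 5)), "undefined AUC")
})

test_that("percentage uncertainty is the absolute metric difference", {
  expect_equal(percentageUncertainty(92.8, 81.0), 11.8)
  expect_equal(percentageUncertainty(77.77, 77.77), 0)
  expect_equal(percentageUncertainty(90.4, 93.3), 2.9)
  expect_equal(percentageUncertainty(89.7, 90.7), 1.0)  # sign is dropped
  expect_equal(percentageUncertainty(1, 2.55, digits = NA), 1.55)
})

test_that("prediction summaries tie mean, entropy, label and certainty", {
  P <- rbind(c(0.5, 0.9, 0.05), c(0.5, 1.0, 0.15))
  s <- summarizePredictions(probabilitySample(P), threshold = 0.30)
  expect_equal(muPred(s), c(0.5, 0.95, 0.1))
  expect_equal(s@entropy[1], log(2))
  expect_equal(entropyNorm(s)[1], 1)
  expect_identical(predictedLabel(s), c(1L, 1L, 0L))
  # normalised entropies: 1, 0.286, 0.469 against threshold 0.30
  expect_identical(isCertain(s), c(FALSE, TRUE, FALSE))
  sLoose <- summarizePredictions(probabilitySample(P), threshold = 0.50)
  expect_identical(isCertain(sLoose), c(FALSE, TRUE, TRUE))
})
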