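## Multi-class orchestration: class rebalancing, One-vs-All binarization,
## per-task train/sample/evaluate loops, and aggregation into delta tables.

#' Balance classes by random oversampling
#'
#' Every minority class is topped up to the pre-balancing maximum count by
#' duplicating (sampling with replacement) its own rows; no synthetic rows
#' are invented. Deterministic under `seed`.
#'
#' @param dataset a [LabeledDataset-class] with at least one instance per
#'   class.
#' @param seed integer RNG seed.
#' @return a [LabeledDataset-class] with equal class counts.
#' @export
oversampleBalance <- function(dataset, seed = 1L) {
  stopifnot(is(dataset, "LabeledDataset"))
  counts <- classCounts(dataset)
  if (any(counts == 0L))
    stop("invalid input: empty class ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  target <- max(counts)
  if (all(counts == target)) return(dataset)
  set.seed(seed)
  extra <- integer(0)
  for (k in seq_along(counts) - 1L) {
    deficit <- target - counts[[k + 1L]]
    if (deficit > 0L) {
      rows <- which(dataset@labels == k)
      # index through sample.int: sample() on a length-1 vector would
      # sample from 1:rows instead of rows itself
      extra <- c(extra, rows[sample.int(length(rows), deficit,
                                        replace = TRUE)])
    }
  }
  labeledDataset(rbind(dataset@features,
                       dataset@features[extra, , drop = FALSE]),
                 c(dataset@labels, dataset@labels[extra]),
                 nClasses = dataset@nClasses)
}

#' Binarize a multi-class dataset for one One-vs-All task
#'
#' Instances of class `k` get label 1, everything else 0. Each instance is
#' positive in exactly one of the `C` tasks.
#'
#' @param dataset a [LabeledDataset-class].
#' @param k positive class index in `0:(C-1)`.
#' @return list with class `"ovaTask"`: `features`, `labels` (0/1),
#'   `positiveClass`, `degenerate` (TRUE when class `k` is absent).
#' @export
binarize <- function(dataset, k) {
  stopifnot(is(dataset, "LabeledDataset"))
  if (length(k) != 1L || is.na(k) || k < 0L || k >= dataset@nClasses)
    stop("invalid parameter: k must lie in 0:(nClasses - 1)")
  y <- as.integer(dataset@labels == k)
  structure(list(features = dataset@features, labels = y,
                 positiveClass = as.integer(k),
                 degenerate = sum(y) == 0L),
            class = "ovaTask")
}

#' Stratified train/test split indices
#'
#' Splits instance indices per stratum so each stratum contributes
#' approximately `trainFrac` of its members to the training set (at least
#' one instance per stratum on each side when the stratum allows it).
#'
#' @param strata vector defining the strata (e.g. the binary task labels).
#' @param trainFrac fraction in (0, 1), default 0.8.
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(strata, trainFrac = 0.8, seed = 1L) {
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("invalid parameter: trainFrac must be in (0, 1)")
  set.seed(seed)
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    nTrain <- round(trainFrac * length(idx))
    nTrain <- max(1L, min(length(idx) - 1L, nTrain))
    if (length(idx) == 1L) nTrain <- 1L
    train <- c(train, sample(idx, nTrain))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(strata), train))
}

uqTechniques <- c("dnn", "mc_dropout", "ensemble", "emc", "bayes")

#' Run one One-vs-All task with one uncertainty-quantification technique
#'
#' Trains the technique's predictor(s) on a stratified train split, draws
#' the stochastic probability sample on the test split, and computes the
#' full metric report: traditional metrics from the predictive-mean labels,
#' uncertainty-aware metrics from the uncertainty confusion matrix at
#' `threshold`, expected calibration error, Brier score and AUC-ROC of the
#' predictive mean.
#'
#' Techniques: `"dnn"` (single deterministic pass, the uncertainty-free
#' baseline), `"mc_dropout"` (T dropout passes of one net), `"ensemble"`
#' (one deterministic pass per member), `"emc"` (dropout passes pooled over
#' members), `"bayes"` (posterior weight draws pooled over an ensemble of
#' mean-field Gaussian networks).
#'
#' @param dataset a [LabeledDataset-class] (already balanced if desired).
#' @param k positive class index.
#' @param technique one of `"dnn"`, `"mc_dropout"`, `"ensemble"`, `"emc"`,
#'   `"bayes"`.
#' @param netSpec a [referenceNetSpec()]; its `inputDim` is overridden by
#'   the dataset's feature dimension.
#' @param cfg a [trainConfig()].
#' @param threshold certainty threshold on normalised entropy (default 0.30).
#' @param passes total stochastic passes `T` (default 50).
#' @param nMembers ensemble size `M` (default 5).
#' @param trainFrac stratified train fraction (default 0.8).
#' @param seed master seed; split, initialisation, training and sampling
#'   seeds are derived from it.
#' @param bins calibration bin count for the expected calibration error.
#' @return one-row `data.frame` (a metric report): identifiers
#'   (`task`, `technique`, `threshold`, `passes`, `members`, `seed`),
#'   traditional metrics (`accuracy`, `f1`, `precision`, `sensitivity`,
#'   `specificity`, `auc_roc`), uncertainty-aware metrics (`u_acc`, `u_f1`,
#'   `u_prec`, `u_sens`, `u_spec`, `u_auc_roc`), `ece`, `brier` and a
#'   `degenerate` flag (TRUE when any metric hit a 0/0 ratio). All metric
#'   values are proportions in [0, 1]. The calibration table is attached as
#'   attribute `"calibration"`.
#' @export
runTask <- function(dataset, k, technique = "mc_dropout",
                    netSpec = referenceNetSpec(), cfg = trainConfig(),
                    threshold = 0.30, passes = 50L, nMembers = 5L,
                    trainFrac = 0.8, seed = 1L, bins = 10L) {
  technique <- match.arg(technique, uqTechniques)
  task <- binarize(dataset, k)
  if (task$degenerate || sum(task$labels == 0L) == 0L)
    stop("degenerate task ", k, ": only one class present")
  seeds <- deriveSeeds(seed, 4L)
  split <- stratifiedSplit(task$labels, trainFrac, seed = seeds[1L])
  Xtr <- task$features[split$train, , drop = FALSE]
  ytr <- task$labels[split$train]
  Xte <- task$features[split$test, , drop = FALSE]
  yte <- task$labels[split$test]
  if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L)
    stop("degenerate task ", k, ": single-class split")
  netSpec$inputDim <- ncol(Xtr)
  cfg$seed <- seeds[3L]
  perMember <- as.integer(ceiling(passes / nMembers))
  ps <- switch(technique,
    dnn = {
      net <- buildReferenceNet(netSpec, seed = seeds[2L])
      net <- trainPredictor(net, Xtr, ytr, cfg)$predictor
      probabilitySample(matrix(predictProb(net, Xte), nrow = 1L))
    },
    mc_dropout = {
      net <- buildReferenceNet(netSpec, seed = seeds[2L])
      net <- trainPredictor(net, Xtr, ytr, cfg)$predictor
      mcDropoutSample(net, Xte, passes = passes, seed = seeds[4L])
    },
    ensemble = {
      ens <- trainEnsemble(netSpec, Xtr, ytr, cfg, nMembers, seed = seeds[2L])
      ensembleSample(ens, Xte)
    },
    emc = {
      ens <- trainEnsemble(netSpec, Xtr, ytr, cfg, nMembers, seed = seeds[2L])
      emcSample(ens, Xte, passesPerMember = perMember, seed = seeds[4L])
    },
    bayes = {
      ens <- trainEnsemble(netSpec, Xtr, ytr, cfg, nMembers, seed = seeds[2L],
                           bayes = TRUE)
      emcSample(ens, Xte, passesPerMember = perMember, seed = seeds[4L])
    })
  summ <- summarizePredictions(ps, threshold)
  trad <- traditionalMetrics(binaryConfusion(predictedLabel(summ), yte))
  um <- uncertaintyMetrics(
    uncertaintyConfusion(predictedLabel(summ), yte, isCertain(summ)))
  cal <- ece(muPred(summ), yte, bins = bins)
  report <- data.frame(
    task = paste0("class", k, "_vs_all"), technique = technique,
    threshold = threshold, passes = nPasses(ps), members = nMembers,
    seed = seed,
    accuracy = trad$accuracy, f1 = trad$f1, precision = trad$precision,
    sensitivity = trad$sensitivity, specificity = trad$specificity,
    auc_roc = aucROC(muPred(summ), yte),
    u_acc = um$uAcc, u_f1 = um$uF1, u_prec = um$uPrec, u_sens = um$uSens,
    u_spec = um$uSpec, u_auc_roc = aucROC(muPred(summ), yte),
    ece = cal$ece, brier = brierScore(muPred(summ), yte),
    degenerate = trad$degenerate || um$degenerate,
    stringsAsFactors = FALSE)
  attr(report, "calibration") <- cal$table
  report
}

#' Percentage-uncertainty delta table
#'
#' Applies [percentageUncertainty()] cell-wise between each
#' uncertainty-aware report and its uncertainty-free baseline of the same
#' task, for the accuracy, AUC-ROC, precision and sensitivity columns
#' (traditional value vs its `u_` counterpart), on the percent scale at
#' 1-decimal reporting precision.
#'
#' @param reports `data.frame` of uncertainty-aware metric reports
#'   (rows from [runTask()], technique != "dnn").
#' @param baseline `data.frame` of baseline reports (technique "dnn"),
#'   one row per task appearing in `reports`.
#' @return `data.frame` with columns `task`, `technique`, `u_acc`,
#'   `u_auc_roc`, `u_prec`, `u_sens` holding the absolute differences in
#'   percentage points.
#' @export
aggregateDeltas <- function(reports, baseline) {
  if (!all(reports$task %in% baseline$task))
    stop("invalid input: baseline missing for task(s) ",
         paste(setdiff(reports$task, baseline$task), collapse = ", "))
  pairs <- rbind(c("accuracy", "u_acc"), c("auc_roc", "u_auc_roc"),
                 c("precision", "u_prec"), c("sensitivity", "u_sens"))
  out <- reports[, c("task", "technique")]
  for (i in seq_len(nrow(pairs))) {
    base <- baseline[[pairs[i, 1L]]][match(reports$task, baseline$task)]
    out[[pairs[i, 2L]]] <- percentageUncertainty(100 * base,
                                                 100 * reports[[pairs[i, 2L]]])
  }
  out
}

#' Build a run manifest
#'
#' A manifest fully determines an experiment: dataset generator spec,
#' techniques, sampler sizes, threshold, split fraction and master seed.
#' Replaying the same manifest reproduces every output table byte for byte.
#'
#' @param syntheticSpec a [syntheticSpec()] describing the dataset (or NULL
#'   when a dataset is passed to [runExperiment()] directly).
#' @param techniques character vector of UQ techniques to evaluate (the
#'   "dnn" baseline is always run).
#' @param threshold,passes,nMembers,trainFrac,bins evaluation parameters.
#' @param oversample logical, balance classes by random oversampling first.
#' @param cfg a [trainConfig()].
#' @param seed master seed.
#' @return list with class `"runManifest"`.
#' @export
runManifest <- function(syntheticSpec = NULL,
                        techniques = c("mc_dropout", "ensemble", "emc",
                                       "bayes"),
                        threshold = 0.30, passes = 50L, nMembers = 5L,
                        trainFrac = 0.8, bins = 10L, oversample = TRUE,
                        cfg = trainConfig(), seed = 1L) {
  techniques <- vapply(techniques, match.arg, "",
                       choices = setdiff(uqTechniques, "dnn"))
  structure(list(syntheticSpec = syntheticSpec, techniques = techniques,
                 threshold = threshold, passes = as.integer(passes),
                 nMembers = as.integer(nMembers), trainFrac = trainFrac,
                 bins = as.integer(bins), oversample = oversample, cfg = cfg,
                 seed = as.integer(seed)),
            class = "runManifest")
}

#' Run a full One-vs-All uncertainty-quantification experiment
#'
#' Optionally balances the dataset by random oversampling, then for every
#' class `k` runs the uncertainty-free baseline and every requested
#' technique via [runTask()], and aggregates the percentage-uncertainty
#' delta table against the baseline.
#'
#' @param manifest a [runManifest()].
#' @param dataset a [LabeledDataset-class]; when NULL it is generated from
#'   the manifest's `syntheticSpec`.
#' @return list with class `"reportBundle"`: `metrics` (one row per task x
#'   technique incl. baseline), `calibration` (per-bin table with task and
#'   technique columns), `deltas` (percentage-uncertainty table), and
#'   `manifest`.
#' @export
runExperiment <- function(manifest, dataset = NULL) {
  stopifnot(inherits(manifest, "runManifest"))
  if (is.null(dataset)) {
    if (is.null(manifest$syntheticSpec))
      stop("invalid input: no dataset and no syntheticSpec in manifest")
    dataset <- makeFeatures(manifest$syntheticSpec)
  }
  if (manifest$oversample)
    dataset <- oversampleBalance(dataset, seed = manifest$seed)
  classes <- seq_len(dataset@nClasses) - 1L
  techniques <- c("dnn", manifest$techniques)
  taskSeeds <- deriveSeeds(manifest$seed,
                           length(classes) * length(techniques))
  metrics <- list(); calib <- list()
  i <- 0L
  for (k in classes) {
    for (tech in techniques) {
      i <- i + 1L
      rep <- runTask(dataset, k, tech, cfg = manifest$cfg,
                     threshold = manifest$threshold,
                     passes = manifest$passes,
                     nMembers = manifest$nMembers,
                     trainFrac = manifest$trainFrac,
                     seed = taskSeeds[i], bins = manifest$bins)
      ct <- attr(rep, "calibration")
      calib[[i]] <- cbind(task = rep$task, technique = tech, ct)
      attr(rep, "calibration") <- NULL
      metrics[[i]] <- rep
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  baseline <- metrics[metrics$technique == "dnn", , drop = FALSE]
  uq <- metrics[metrics$technique != "dnn", , drop = FALSE]
  list(metrics = metrics, calibration = do.call(rbind, calib),
       deltas = aggregateDeltas(uq, baseline), manifest = manifest) |>
    structure(class = "reportBundle")
}
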