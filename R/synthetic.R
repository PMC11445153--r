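## Synthetic fixtures: class-conditional Gaussian feature data with
## controllable inter-class overlap, and probability/label fixtures with
## known calibration.

#' Specification for a synthetic multi-class feature dataset
#'
#' Class-conditional spherical Gaussians whose means sit at mutual Euclidean
#' distance `separation` (on the scaled coordinate axes of the first `C`
#' feature dimensions, a regular simplex). `separation / sigma` controls the
#' aleatoric overlap: 0 means the classes are indistinguishable, 10 means
#' near-perfect separability. The defaults emulate a moderately imbalanced
#' three-class extracted-feature table (732 / 619 / 526 instances, 150
#' features) with enough overlap that a trained classifier lands in the
#' realistic low-90s accuracy band.
#'
#' @param counts integer vector of per-class instance counts (class `k`
#'   is position `k + 1`).
#' @param nFeatures feature dimension `d` (default 150).
#' @param separation mutual distance between class means (default 3).
#' @param sigma within-class standard deviation (> 0, default 1).
#' @param seed integer RNG seed.
#' @return list with class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(counts = c(732L, 619L, 526L), nFeatures = 150L,
                          separation = 3, sigma = 1, seed = 1L) {
  if (any(counts < 1L)) stop("invalid spec: counts must be >= 1")
  if (sigma <= 0) stop("invalid spec: sigma must be > 0")
  if (separation < 0) stop("invalid spec: separation must be >= 0")
  if (nFeatures < length(counts))
    stop("invalid spec: need nFeatures >= number of classes")
  structure(list(counts = as.integer(counts),
                 nFeatures = as.integer(nFeatures),
                 separation = separation, sigma = sigma,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Generate class-conditional Gaussian features
#'
#' Class `k`'s mean is `separation / sqrt(2)` times the `k`-th coordinate
#' axis, so all pairwise mean distances equal `separation`; features are
#' i.i.d. Gaussian with spread `sigma` around the class mean. Instances are
#' emitted grouped by class; generation is bit-reproducible under the spec's
#' seed.
#'
#' @param spec a [syntheticSpec()].
#' @return a [LabeledDataset-class] with exact per-class counts.
#' @examples
#' ds <- makeFeatures(syntheticSpec(counts = c(40, 30, 30), nFeatures = 10))
#' classCounts(ds)
#' @export
makeFeatures <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  C <- length(spec$counts)
  n <- sum(spec$counts)
  X <- matrix(rnorm(n * spec$nFeatures, sd = spec$sigma), n, spec$nFeatures)
  lab <- rep(seq_len(C) - 1L, spec$counts)
  shift <- spec$separation / sqrt(2)
  for (k in seq_len(C))
    X[lab == k - 1L, k] <- X[lab == k - 1L, k] + shift
  labeledDataset(X, lab, nClasses = C)
}

#' Generate a fixture with known perfect calibration
#'
#' Draws `mu` uniformly on [0, 1] and labels as Bernoulli(`mu`), so
#' `P(y = 1 | mu) = mu` by construction and the empirical calibration curve
#' approaches the identity as `n` grows (expected calibration error tends
#' to 0).
#'
#' @param n number of instances.
#' @param seed integer RNG seed.
#' @return list with class `"calibratedFixture"`: `mu` (numeric), `label`
#'   (0/1 integer), `seed`.
#' @export
makeCalibrated <- function(n, seed = 1L) {
  if (n < 1L) stop("invalid parameter: n must be >= 1")
  set.seed(seed)
  mu <- runif(n)
  list(mu = mu, label = as.integer(rbinom(n, 1L, mu)), seed = as.integer(seed))
}

#' Write / read a LabeledDataset as CSV
#'
#' Columns `feat_0 .. feat_{d-1}` and `label`.
#'
#' @param dataset a [LabeledDataset-class].
#' @param path file path.
#' @return `writeDatasetCsv` returns `path` invisibly; `readDatasetCsv`
#'   returns a [LabeledDataset-class].
#' @export
writeDatasetCsv <- function(dataset, path) {
  stopifnot(is(dataset, "LabeledDataset"))
  df <- as.data.frame(dataset@features)
  names(df) <- paste0("feat_", seq_len(ncol(df)) - 1L)
  df$label <- dataset@labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDatasetCsv
#' @export
readDatasetCsv <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("parse error: no 'label' column in ", path)
  labeledDataset(as.matrix(df[setdiff(names(df), "label")]), df$label)
}
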