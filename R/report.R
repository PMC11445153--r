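## Report writers, per-pass probability table IO, and reproduction of the
## published percentage-uncertainty delta tables from their printed metric
## values.

#' Write a report bundle to delimited tables
#'
#' Writes `metrics.csv` (one row per task x technique, metric values on the
#' percent scale rounded to 1 decimal; `ece` and `brier` stay on the unit
#' scale), `calibration.csv` (per-bin table), `deltas.csv`
#' (percentage-uncertainty table) and `manifest.json` into `dir`.
#'
#' @param bundle a `"reportBundle"` from [runExperiment()].
#' @param dir output directory (created if missing).
#' @return the paths written, invisibly.
#' @export
writeReportBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "reportBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- bundle$metrics
  pctCols <- c("accuracy", "f1", "precision", "sensitivity", "specificity",
               "auc_roc", "u_acc", "u_f1", "u_prec", "u_sens", "u_spec",
               "u_auc_roc")
  m[pctCols] <- lapply(m[pctCols], function(v) round(100 * v, 1))
  m$ece <- round(m$ece, 4)
  m$brier <- round(m$brier, 4)
  paths <- file.path(dir, c("metrics.csv", "calibration.csv", "deltas.csv",
                            "manifest.json"))
  utils::write.csv(m, paths[1L], row.names = FALSE)
  utils::write.csv(bundle$calibration, paths[2L], row.names = FALSE)
  utils::write.csv(bundle$deltas, paths[3L], row.names = FALSE)
  manifest <- bundle$manifest
  manifest$cfg <- unclass(manifest$cfg)
  if (!is.null(manifest$syntheticSpec))
    manifest$syntheticSpec <- unclass(manifest$syntheticSpec)
  jsonlite::write_json(unclass(manifest), paths[4L], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Write / read a per-pass probability table
#'
#' The long delimited exchange format consumed by the metric layer:
#' columns `instance_id`, `pass`, `prob`, `label`.
#'
#' @param samples a [ProbabilitySample-class].
#' @param truth 0/1 label vector, one per instance.
#' @param path file path (`.csv` comma-separated, anything else
#'   tab-separated).
#' @return `writeProbabilityTable` returns `path` invisibly;
#'   `readProbabilityTable` returns a list with `samples`
#'   (a [ProbabilitySample-class]) and `labels`.
#' @export
writeProbabilityTable <- function(samples, truth, path) {
  stopifnot(is(samples, "ProbabilitySample"),
            length(truth) == nInstances(samples))
  P <- probs(samples)
  df <- data.frame(
    instance_id = rep(seq_len(ncol(P)), each = nrow(P)),
    pass = rep(seq_len(nrow(P)), times = ncol(P)),
    prob = as.vector(P),
    label = rep(as.integer(truth), each = nrow(P)))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProbabilityTable
#' @export
readProbabilityTable <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE)
  need <- c("instance_id", "pass", "prob", "label")
  if (!all(need %in% names(df)))
    stop("parse error: expected columns ", paste(need, collapse = ", "))
  ids <- sort(unique(df$instance_id))
  passes <- sort(unique(df$pass))
  P <- matrix(NA_real_, length(passes), length(ids))
  P[cbind(match(df$pass, passes), match(df$instance_id, ids))] <- df$prob
  if (anyNA(P)) stop("parse error: incomplete pass x instance grid")
  lab <- df$label[match(ids, df$instance_id)]
  list(samples = probabilitySample(P), labels = as.integer(lab))
}

#' Reproduce percentage-uncertainty delta tables from printed metric values
#'
#' Takes a long-format table of published OvA metric values — rows with
#' `model = "DNN"` carry the traditional metrics (percent scale), rows for
#' the uncertainty-aware models carry `u_`-prefixed metrics — and applies
#' [percentageUncertainty()] cell-wise between each uncertainty-aware model
#' and the DNN baseline of the same class, for accuracy, AUC-ROC, precision
#' and sensitivity.
#'
#' @param fixture path to the fixture CSV, or a `data.frame` with columns
#'   `class`, `model`, `auc_roc`, `accuracy`, `precision`, `sensitivity`
#'   (DNN rows) and `u_acc`, `u_auc_roc`, `u_prec`, `u_sens` (model rows).
#'   Defaults to the published-values fixture shipped with the package.
#' @return `data.frame` with columns `class`, `model`, `u_acc`,
#'   `u_auc_roc`, `u_prec`, `u_sens` in percentage points (1 decimal).
#' @examples
#' head(reproduceTables())
#' @export
reproduceTables <- function(fixture = system.file("extdata",
                                                  "published_ova_metrics.csv",
                                                  package = "ovaUQ")) {
  df <- if (is.data.frame(fixture)) fixture else {
    if (!file.exists(fixture)) stop("parse error: fixture not found: ", fixture)
    utils::read.csv(fixture)
  }
  need <- c("class", "model")
  if (!all(need %in% names(df)))
    stop("parse error: fixture needs 'class' and 'model' columns")
  base <- df[df$model == "DNN", , drop = FALSE]
  uq <- df[df$model != "DNN", , drop = FALSE]
  if (nrow(base) == 0L || nrow(uq) == 0L)
    stop("parse error: fixture needs both DNN and uncertainty-aware rows")
  miss <- setdiff(uq$class, base$class)
  if (length(miss))
    stop("parse error: no DNN baseline for class(es) ",
         paste(miss, collapse = ", "), " (row ids ",
         paste(which(df$class %in% miss & df$model != "DNN"),
               collapse = ", "), ")")
  pairs <- rbind(c("accuracy", "u_acc"), c("auc_roc", "u_auc_roc"),
                 c("precision", "u_prec"), c("sensitivity", "u_sens"))
  out <- uq[, c("class", "model")]
  for (i in seq_len(nrow(pairs))) {
    b <- base[[pairs[i, 1L]]][match(uq$class, base$class)]
    out[[pairs[i, 2L]]] <- percentageUncertainty(b, uq[[pairs[i, 2L]]])
  }
  rownames(out) <- NULL
  out
}

#' Published delta-table values shipped as a fixture
#'
#' Returns the printed percentage-uncertainty tables in long format with a
#' `consistent` flag marking the one cell whose printed value does not equal
#' the difference of its printed operands.
#'
#' @return `data.frame` with columns `class`, `model`, `metric`, `value`,
#'   `consistent`.
#' @export
publishedDeltas <- function() {
  utils::read.csv(system.file("extdata", "published_ova_deltas.csv",
                              package = "ovaUQ"))
}
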