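# Evaluation metrics with multi-task missing-target masking.

#' Root mean squared error
#' @param pred,target Numeric vectors (NAs in target are dropped).
#' @return Scalar.
#' @export
rmseScore <- function(pred, target) {
  ok <- !is.na(target)
  sqrt(mean((pred[ok] - target[ok]) ^ 2))
}

#' Mean absolute error
#' @param pred,target Numeric vectors (NAs in target are dropped).
#' @return Scalar.
#' @export
maeScore <- function(pred, target) {
  ok <- !is.na(target)
  mean(abs(pred[ok] - target[ok]))
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic (ties handled by midranks),
#' equivalent to step-function integration of the ROC curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels (NAs dropped).
#' @return Scalar in [0, 1]; NA when only one class is present.
#' @export
aurocScore <- function(scores, labels) {
  ok <- !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: step-function integration of the precision-recall
#' curve, with ties broken by a stable descending-score sort.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels (NAs dropped).
#' @return Scalar in (0, 1]; NA when no positives are present.
#' @export
auprcScore <- function(scores, labels) {
  ok <- !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  npos <- sum(labels == 1)
  if (npos == 0 || sum(labels == 0) == 0) return(NA_real_)
  o <- order(-scores)  # stable
  lab <- labels[o]
  cumPos <- cumsum(lab)
  prec <- cumPos / seq_along(lab)
  sum(prec[lab == 1]) / npos
}

#' Compute a metric over (possibly multi-task) predictions
#'
#' Tasks are scored independently on their non-missing targets and averaged
#' with equal weight. AUROC/AUPRC tasks that lack one of the two classes are
#' skipped with a warning.
#'
#' @param predictions Numeric vector or matrix (rows = molecules, columns =
#'   tasks).
#' @param targets Same shape; NA marks a missing target.
#' @param metric One of \code{"rmse"}, \code{"mae"}, \code{"auroc"},
#'   \code{"auprc"}.
#' @return Scalar: unweighted mean of per-task scores.
#' @examples
#' computeMetric(c(1, 2), c(1, 4), "rmse")  # sqrt(2)
#' @export
computeMetric <- function(predictions, targets,
                          metric = c("rmse", "mae", "auroc", "auprc")) {
  metric <- match.arg(metric)
  predictions <- as.matrix(predictions)
  targets <- as.matrix(targets)
  stopifnot(all(dim(predictions) == dim(targets)))
  fn <- switch(metric, rmse = rmseScore, mae = maeScore,
               auroc = aurocScore, auprc = auprcScore)
  vals <- numeric(0)
  for (k in seq_len(ncol(targets))) {
    tk <- targets[, k]
    if (all(is.na(tk))) next
    v <- fn(predictions[, k], tk)
    if (is.na(v)) {
      warning("task ", k, " skipped: only one class present", call. = FALSE)
      next
    }
    vals <- c(vals, v)
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Is a higher metric value better?
#' @param metric Metric name.
#' @return Logical.
#' @export
metricMaximized <- function(metric) metric %in% c("auroc", "auprc")
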