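#' Confusion counts for binary seizure labels
#'
#' The positive class is seizure (= 1).
#'
#' @param pred,truth integer vectors of 0/1 labels, equal length.
#' @return list with integer elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth))
    gf_stop("gatformer_shape_error", "pred and truth lengths differ")
  if (!all(pred %in% 0:1) || !all(truth %in% 0:1))
    gf_stop("gatformer_shape_error", "labels must be 0 or 1")
  list(TP = sum(pred == 1 & truth == 1), FP = sum(pred == 1 & truth == 0),
       TN = sum(pred == 0 & truth == 0), FN = sum(pred == 0 & truth == 1))
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP + TN) / total`, sensitivity (recall) `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)` and F1, the harmonic mean of precision
#' `TP / (TP + FP)` and recall. Metrics with a zero denominator are reported
#' as 0 with a warning, never NaN.
#'
#' @param cc confusion counts from [confusion_counts()].
#' @return named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `f1` (all in `[0, 1]`).
#' @export
binary_metrics <- function(cc) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  acc <- safe_ratio(cc$TP + cc$TN, total, "accuracy")
  sens <- safe_ratio(cc$TP, cc$TP + cc$FN, "sensitivity")
  spec <- safe_ratio(cc$TN, cc$TN + cc$FP, "specificity")
  prec <- safe_ratio(cc$TP, cc$TP + cc$FP, "precision (for F1)")
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  c(accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation with midrank tie correction, which
#' equals the trapezoidal area under the empirical ROC curve and the
#' proportion of concordant positive/negative score pairs (ties counting
#' one half).
#'
#' @param scores positive-class probabilities or any monotone scores.
#' @param truth 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0)
    gf_stop("gatformer_auc_error", "AUC needs both classes present")
  r <- rank(scores) # midranks handle ties
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate per-fold metrics into a report
#'
#' @param folds list of fold results, each a list with elements `fold`,
#'   `counts` (confusion counts), `metrics` (named vector including `auc`),
#'   and `scores`/`truth`.
#' @return an `eval_report`: per-fold metric table plus mean and population
#'   (divide-by-k) standard deviation per metric.
#' @export
aggregate_report <- function(folds) {
  if (length(folds) < 1)
    gf_stop("gatformer_shape_error", "need at least one fold")
  tab <- do.call(rbind, lapply(folds, function(f) f$metrics))
  rownames(tab) <- vapply(folds, function(f) sprintf("fold%02d", f$fold), "")
  mu <- colMeans(tab)
  sdv <- sqrt(colMeans(sweep(tab, 2, mu)^2))
  structure(list(per_fold = tab, mean = mu, sd = sdv, folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds (values in %%, mean +/- sd)\n",
              nrow(x$per_fold)))
  for (m in colnames(x$per_fold))
    cat(sprintf("  %-12s %6.2f +/- %.2f\n", m, 100 * x$mean[m], 100 * x$sd[m]))
  invisible(x)
}

#' Write an evaluation report to CSV and/or JSON
#'
#' The CSV has one row per fold plus `mean` and `sd` rows, with metric values
#' as percentages rounded to two decimals; the JSON carries the same content
#' unrounded.
#'
#' @param report an `eval_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the list of written paths.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- rbind(report$per_fold, mean = report$mean, sd = report$sd)
    out <- data.frame(fold = rownames(tab),
                      round(100 * tab, 2), check.names = FALSE)
    write.csv(out, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_fold = as.data.frame(report$per_fold),
           mean = as.list(report$mean), sd = as.list(report$sd)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}
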