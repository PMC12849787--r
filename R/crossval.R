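#' Stratified k-fold assignment
#'
#' Distributes each class's samples across `k` folds as evenly as possible
#' (per-fold class counts differ by at most one). `"block"` keeps each
#' class's samples in temporal order and cuts contiguous chunks, so
#' overlapping windows rarely straddle a train/test boundary; `"random"`
#' shuffles within class first. Deterministic given `seed`.
#'
#' @param labels 0/1 vector of sample labels.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param method `"block"` or `"random"`.
#' @return list of `k` disjoint integer index vectors (the test sets), whose
#'   union is all samples.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1L,
                             method = c("block", "random")) {
  method <- match.arg(method)
  folds <- vector("list", k)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      gf_stop("gatformer_stratification_error",
              "class %s has %d samples, fewer than k = %d",
              cls, length(idx), k)
    if (method == "random")
      idx <- local_seed(seed + as.integer(cls), sample(idx))
    cuts <- floor(seq(0, length(idx), length.out = k + 1))
    # rotate which folds get the larger chunks, per class, seeded
    rot <- local_seed(seed + 100L + as.integer(cls), sample.int(k, 1)) - 1L
    for (f in seq_len(k)) {
      g <- ((f - 1L + rot) %% k) + 1L
      if (cuts[f + 1] > cuts[f])
        folds[[g]] <- c(folds[[g]], idx[(cuts[f] + 1):cuts[f + 1]])
    }
  }
  lapply(folds, sort)
}

fold_result <- function(f, p, truth) {
  pred <- as.integer(p >= 0.5)
  cc <- confusion_counts(pred, truth)
  list(fold = f, counts = cc,
       metrics = c(binary_metrics(cc), auc = roc_auc(p, truth)),
       scores = p, truth = truth)
}

zscore_fit_subset <- function(ws, widx) {
  d <- dim(ws$data)
  flat <- ws$data[, , widx, drop = FALSE]
  dim(flat) <- c(d[1], d[2] * length(widx))
  m <- rowMeans(flat)
  s <- sqrt(pmax(rowMeans(flat^2) - m^2, 0))
  list(mean = m, sd = pmax(s, 1e-8))
}

#' Stratified k-fold cross-validation of the seizure detector
#'
#' The full single-subject protocol: window graphs are built once; sequence
#' samples are assigned to stratified folds; within each fold the z-score
#' statistics come from the training windows only, the training samples are
#' balanced 1:1 by oversampling (test folds are never resampled), a fresh
#' model is trained in the configured ablation mode, and the untouched test
#' fold is scored.
#'
#' @param ws a labelled [window_set] for one subject.
#' @param config a [gatformer_config()] (its `mode` selects combined /
#'   gat_only / transformer_only).
#' @param verbose print per-fold progress.
#' @return an object of class `gatformer_cv`: the `eval_report` (per-fold and
#'   mean +/- sd accuracy, sensitivity, specificity, F1, AUC), the fold
#'   assignment, and the configuration.
#' @export
gatformer_cv <- function(ws, config = gatformer_config(), verbose = FALSE) {
  if (!inherits(ws, "window_set"))
    gf_stop("gatformer_format_error", "`ws` must be a window_set")
  d <- dim(ws$data)
  Abank <- build_graph_bank(ws, config$tau)
  sq <- build_sequences(ws$labels, config$n_seq)
  folds <- stratified_kfold(sq$labels, config$n_folds, config$seed,
                            config$fold_method)
  results <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(sq$labels), test)
    stats <- zscore_fit_subset(ws, unique(as.vector(sq$idx[train, ])))
    take <- train[balance_indices(sq$labels[train], config$seed + f)]
    params <- init_model_params(config, d[1], d[2], config$seed + 1000L * f)
    if (config$epochs > 0) {
      fit <- train_model(params, ws$data, Abank,
                         sq$idx[take, , drop = FALSE], sq$labels[take],
                         stats$mean, stats$sd, config)
      params <- fit$params
    }
    p <- engine_predict(params, ws$data, Abank,
                        sq$idx[test, , drop = FALSE],
                        stats$mean, stats$sd, config)
    results[[f]] <- fold_result(f, p, sq$labels[test])
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.3f", f, length(folds),
                      results[[f]]$metrics["accuracy"]))
  }
  structure(list(report = aggregate_report(results), folds = folds,
                 config = config, n_samples = length(sq$labels),
                 class_counts = table(sq$labels)),
            class = "gatformer_cv")
}

#' @export
print.gatformer_cv <- function(x, ...) {
  cat(sprintf("<gatformer_cv> %s model, %d-fold CV on %d samples (%s)\n",
              x$config$mode, length(x$folds), x$n_samples,
              paste(sprintf("%s: %d", names(x$class_counts), x$class_counts),
                    collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' @export
summary.gatformer_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics (%):\n")
  print(round(100 * object$report$per_fold, 2))
  invisible(object)
}

#' Accuracy of an untrained (randomly initialised) model
#'
#' Scores the sequence samples of `ws` with a freshly initialised model in
#' the given mode, without any training — the chance-level reference a
#' trained model must beat.
#'
#' @param ws a labelled [window_set].
#' @param config a [gatformer_config()]; its `mode` selects the architecture.
#' @return accuracy in `[0, 1]`.
#' @export
untrained_accuracy <- function(ws, config = gatformer_config()) {
  config$epochs <- 0
  m <- gatformer(ws, config, balance = FALSE)
  p <- predict(m, ws)
  truth <- predict(m, ws, type = "sequence_labels")
  mean(as.integer(p >= 0.5) == truth)
}
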