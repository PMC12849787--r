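#' Fit a spatiotemporal seizure detector
#'
#' Trains the configured model on a labelled [window_set]: each window
#' becomes a functional-connectivity channel graph (Pearson correlation
#' thresholded at `tau`), sequences of `n_seq` consecutive windows are the
#' classification samples (label = majority of window labels, ties counting
#' as seizure), classes are balanced 1:1 by oversampling the minority, and
#' the model is optimised with Adam under focal loss. Per-channel z-score
#' statistics are fitted on the supplied windows and stored for prediction.
#' With `epochs = 0` in the configuration the returned model keeps its random
#' initialization (an untrained baseline).
#'
#' @param ws a labelled [window_set] (the training data).
#' @param config a [gatformer_config()].
#' @param balance balance classes 1:1 by oversampling before training
#'   (default `TRUE`; requires both classes present).
#' @return an object of class `gatformer` with methods [predict.gatformer()],
#'   `print`, `summary`, `plot` (loss curve) and `coef` (parameter tensors).
#' @export
#' @seealso [gatformer_cv()] for the cross-validated protocol.
gatformer <- function(ws, config = gatformer_config(), balance = TRUE) {
  if (!inherits(ws, "window_set"))
    gf_stop("gatformer_format_error", "`ws` must be a window_set")
  d <- dim(ws$data)
  Abank <- build_graph_bank(ws, config$tau)
  sq <- build_sequences(ws$labels, config$n_seq)
  stats <- zscore_fit(ws)
  take <- if (balance) balance_indices(sq$labels, config$seed) else
    seq_along(sq$labels)
  params <- init_model_params(config, d[1], d[2], config$seed)
  history <- numeric(0)
  if (config$epochs > 0) {
    fit <- train_model(params, ws$data, Abank,
                       sq$idx[take, , drop = FALSE], sq$labels[take],
                       stats$mean, stats$sd, config)
    params <- fit$params
    history <- fit$loss_history
  }
  structure(list(params = params, config = config, norm_stats = stats,
                 loss_history = history,
                 n_channels = d[1], n_features = d[2],
                 channel_labels = ws$channel_labels,
                 n_train = length(take), call = match.call()),
            class = "gatformer")
}

sequences_for_predict <- function(object, ws) {
  d <- dim(ws$data)
  if (d[1] != object$n_channels || d[2] != object$n_features)
    gf_stop("gatformer_shape_error",
            "window shape %dx%d does not match the fitted model (%dx%d)",
            d[1], d[2], object$n_channels, object$n_features)
  build_sequences(ws$labels, object$config$n_seq)
}

#' Predict seizure probabilities for new windows
#'
#' Windows are turned into graphs and sequences exactly as during fitting,
#' normalised with the statistics stored in the model, and scored by a
#' deterministic (dropout-free) forward pass.
#'
#' @param object a fitted [gatformer()] model.
#' @param newdata a [window_set] with the same window shape.
#' @param type `"prob"` for seizure probabilities per sequence sample,
#'   `"class"` for 0/1 labels (threshold 0.5), or `"sequence_labels"` for the
#'   reference labels of the sequence samples.
#' @param ... unused.
#' @return numeric or integer vector, one entry per sequence sample.
#' @export
predict.gatformer <- function(object, newdata, type = c("prob", "class",
                                                        "sequence_labels"),
                              ...) {
  type <- match.arg(type)
  sq <- sequences_for_predict(object, newdata)
  if (type == "sequence_labels") return(sq$labels)
  Abank <- build_graph_bank(newdata, object$config$tau)
  p <- engine_predict(object$params, newdata$data, Abank, sq$idx,
                      object$norm_stats$mean, object$norm_stats$sd,
                      object$config)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
print.gatformer <- function(x, ...) {
  cat(sprintf("<gatformer> %s model, %d channels x %d samples/window, n_seq %d\n",
              x$config$mode, x$n_channels, x$n_features, x$config$n_seq))
  if (length(x$loss_history)) {
    cat(sprintf("  trained on %d samples, %d epochs; focal loss %.4f -> %.4f\n",
                x$n_train, length(x$loss_history),
                x$loss_history[1], x$loss_history[length(x$loss_history)]))
  } else {
    cat("  untrained (randomly initialised)\n")
  }
  invisible(x)
}

#' @export
summary.gatformer <- function(object, ...) {
  np <- sum(vapply(object$params, length, 1))
  cat(sprintf("Seizure detector (%s): %s parameters in %d tensors\n",
              object$config$mode, format(np, big.mark = ","),
              length(object$params)))
  print(object$config)
  if (length(object$loss_history))
    cat(sprintf("Final training focal loss: %.5f\n",
                object$loss_history[length(object$loss_history)]))
  invisible(object)
}

#' @export
coef.gatformer <- function(object, ...) object$params

#' Plot the training loss curve
#' @param x a fitted [gatformer()] model.
#' @param ... passed to [plot()].
#' @export
plot.gatformer <- function(x, ...) {
  if (!length(x$loss_history)) {
    warning("untrained model: no loss history to plot")
    return(invisible(x))
  }
  plot(seq_along(x$loss_history), x$loss_history, type = "b",
       xlab = "epoch", ylab = "mean focal loss", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of every parameter tensor plus the
#' configuration and normalization statistics, sufficient to reproduce
#' predictions exactly.
#'
#' @param object a fitted [gatformer()] model.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(object, path) {
  if (!inherits(object, "gatformer"))
    gf_stop("gatformer_io_error", "`object` must be a gatformer model")
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "gatformer"))
    gf_stop("gatformer_io_error", "'%s' is not a gatformer checkpoint", path)
  obj
}
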