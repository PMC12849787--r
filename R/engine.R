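# R-side wrappers around the compiled batched engine.

#' Build classification sequences from consecutive windows
#'
#' A classification sample is `n_seq` consecutive windows (stride one window
#' step); its label is the majority of the window labels, with ties counting
#' as seizure.
#'
#' @param labels per-window 0/1 labels.
#' @param n_seq windows per sample.
#' @return list with `idx` (samples x n_seq matrix of window indices) and
#'   `labels` (per-sample 0/1).
#' @export
build_sequences <- function(labels, n_seq) {
  K <- length(labels)
  if (K < n_seq)
    gf_stop("gatformer_shape_error",
            "%d windows cannot form a sequence of %d", K, n_seq)
  S <- K - n_seq + 1
  idx <- outer(seq_len(S), seq_len(n_seq) - 1L, `+`)
  frac <- as.vector(stats::filter(labels, rep(1 / n_seq, n_seq), sides = 1))
  seq_lab <- as.integer(frac[seq(n_seq, K)] >= 0.5 - 1e-12)
  list(idx = idx, labels = seq_lab)
}

engine_cfg <- function(cfg, training, compute_grads, dropout_seed = 0) {
  list(mode = cfg$mode, training = training, compute_grads = compute_grads,
       negative_slope = cfg$negative_slope, focal_alpha = cfg$focal_alpha,
       focal_gamma = cfg$focal_gamma, dropout = cfg$dropout,
       act = match(cfg$activation, c("elu", "relu", "identity")) - 1L,
       n_heads_t = cfg$t_heads, L = cfg$L,
       Epos = positional_encoding(cfg$n_seq + 1, cfg$D),
       dropout_seed = as.numeric(dropout_seed))
}

# Predict seizure probabilities for sequence samples, in inference batches.
engine_predict <- function(params, Xbank, Abank, seq_idx, mu, sdv, cfg,
                           batch = 256L) {
  S <- nrow(seq_idx)
  ec <- engine_cfg(cfg, training = FALSE, compute_grads = FALSE)
  p <- numeric(S)
  for (b0 in seq(1, S, by = batch)) {
    b1 <- min(b0 + batch - 1, S)
    out <- .engine_run(params, Xbank, Abank,
                       seq_idx[b0:b1, , drop = FALSE], mu, sdv,
                       integer(b1 - b0 + 1), ec)
    p[b0:b1] <- out$p
  }
  p
}

adam_init <- function(params) {
  zeros <- lapply(params, function(x) x * 0)
  list(m = zeros, v = zeros, t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    dim(g) <- dim(state$m[[nm]]) # engine returns vectors as n x 1 matrices
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train a model on sequence samples with Adam and focal loss
#'
#' Mini-batch Adam (learning rate, batch size, epoch count from `cfg`)
#' minimising the focal loss; per-epoch shuffling and dropout are seeded, so
#' identical inputs and seeds give identical parameters.
#'
#' @param params initial flat parameter list from [init_model_params()].
#' @param Xbank channels x samples x windows array of raw window data.
#' @param Abank channels x channels x windows adjacency array.
#' @param seq_idx samples x n_seq matrix of window indices (training samples,
#'   already balanced).
#' @param labels per-sample 0/1 labels.
#' @param mu,sdv per-channel normalization statistics (fitted on training
#'   data only).
#' @param cfg a [gatformer_config()].
#' @return list with trained `params` and `loss_history` (mean focal loss per
#'   epoch).
#' @export
train_model <- function(params, Xbank, Abank, seq_idx, labels, mu, sdv, cfg) {
  S <- nrow(seq_idx)
  history <- numeric(cfg$epochs)
  step <- 0L
  local_seed(cfg$seed, {
    state <- adam_init(params)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(S)
      losses <- c()
      for (b0 in seq(1, S, by = cfg$batch_size)) {
        take <- ord[b0:min(b0 + cfg$batch_size - 1, S)]
        step <- step + 1L
        ec <- engine_cfg(cfg, training = TRUE, compute_grads = TRUE,
                         dropout_seed = (cfg$seed * 100003 + step) %% 2^31)
        out <- .engine_run(params, Xbank, Abank,
                           seq_idx[take, , drop = FALSE], mu, sdv,
                           as.integer(labels[take]), ec)
        if (!is.finite(out$loss))
          gf_stop("gatformer_training_error",
                  "training diverged (non-finite loss) at epoch %d", epoch)
        upd <- adam_update(params, out$grads, state, cfg$lr)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, out$loss)
      }
      history[epoch] <- mean(losses)
    }
  })
  list(params = params, loss_history = history)
}
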