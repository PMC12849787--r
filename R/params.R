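# Trainable tensors are kept as a flat named list (the "checkpoint" form the
# compiled engine consumes). Initialization goes through the reference
# constructors so the flat and structured forms are always consistent.

# per-head GAT tensors -> flat matrices with heads stacked along columns
flatten_gat_layer <- function(lp) {
  f_out <- ncol(lp$W[[1]])
  list(W = do.call(cbind, lp$W),
       a1 = vapply(lp$a, function(a) a[seq_len(f_out)], numeric(f_out)),
       a2 = vapply(lp$a, function(a) a[f_out + seq_len(f_out)], numeric(f_out)))
}

unflatten_gat_layer <- function(W, a1, a2, negative_slope, activation) {
  Q <- ncol(a1)
  f_out <- nrow(a1)
  structure(list(
    W = lapply(seq_len(Q), function(q) W[, (q - 1) * f_out + seq_len(f_out), drop = FALSE]),
    a = lapply(seq_len(Q), function(q) c(a1[, q], a2[, q])),
    n_heads = Q, negative_slope = negative_slope, activation = activation
  ), class = "gat_layer_params")
}

#' Initialize all trainable tensors for one model
#'
#' Builds the flat parameter list for the configured ablation mode:
#' `"combined"` (GAT encoder + Transformer), `"gat_only"` (GAT encoder +
#' mean-pool + linear head) or `"transformer_only"` (raw window slices
#' tokenized directly). Xavier-uniform initialization under a private seed.
#'
#' @param cfg a [gatformer_config()].
#' @param n_channels,n_features window shape (channels, samples per window).
#' @param seed integer seed.
#' @return named list of parameter tensors with attribute `meta` recording
#'   the dimensions.
#' @export
init_model_params <- function(cfg, n_channels, n_features, seed = 1L) {
  local_seed(seed, {
    p <- list()
    f_tok <- n_features # per-node feature dim entering the tokenizer
    if (cfg$mode != "transformer_only") {
      enc <- gat_encoder_params(n_features, cfg$gat_hidden, cfg$gat_out,
                                cfg$gat_heads,
                                negative_slope = cfg$negative_slope,
                                activation = cfg$activation,
                                dropout_rate = cfg$dropout)
      l1 <- flatten_gat_layer(enc$layer1)
      l2 <- flatten_gat_layer(enc$layer2)
      p$gW1 <- l1$W; p$ga1_1 <- l1$a1; p$ga2_1 <- l1$a2
      p$gW2 <- l2$W; p$ga1_2 <- l2$a1; p$ga2_2 <- l2$a2
      f_tok <- cfg$gat_out
    }
    if (cfg$mode != "gat_only") {
      tp <- transformer_params(n_channels * f_tok, cfg$n_seq, cfg$D,
                               cfg$t_heads, cfg$mlp_hidden, cfg$L,
                               dropout_rate = cfg$dropout)
      p$E <- tp$E
      p$cls <- tp$cls
      for (l in seq_len(cfg$L)) {
        b <- tp$blocks[[l]]
        pre <- sprintf("b%d_", l - 1)
        for (nm in names(b)) # ln1_g -> ln1g etc.: flat names drop the underscore
          p[[paste0(pre, gsub("^(ln[12f]?)_", "\\1", nm))]] <- b[[nm]]
      }
      p$lnfg <- tp$lnf_g; p$lnfb <- tp$lnf_b
      p$headW <- tp$head_W; p$headb <- tp$head_b
    } else {
      p$headW <- xavier_uniform(cfg$gat_out, 2)
      p$headb <- rep(0, 2)
    }
    attr(p, "meta") <- list(n_channels = n_channels, n_features = n_features,
                            f_tok = f_tok, mode = cfg$mode, seed = seed)
    p
  })
}

# Structured views of the flat checkpoint, for the plain-R reference path.
params_to_gat_encoder <- function(p, cfg) {
  structure(list(
    layer1 = unflatten_gat_layer(p$gW1, p$ga1_1, p$ga2_1,
                                 cfg$negative_slope, cfg$activation),
    layer2 = unflatten_gat_layer(p$gW2, p$ga1_2, p$ga2_2,
                                 cfg$negative_slope, cfg$activation),
    dropout_rate = cfg$dropout
  ), class = "gat_encoder_params")
}

params_to_transformer <- function(p, cfg) {
  blocks <- lapply(seq_len(cfg$L) - 1, function(l) {
    pre <- sprintf("b%d_", l)
    list(ln1_g = p[[paste0(pre, "ln1g")]],
         ln1_b = p[[paste0(pre, "ln1b")]],
         Wqkv = p[[paste0(pre, "Wqkv")]], bqkv = p[[paste0(pre, "bqkv")]],
         Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]],
         ln2_g = p[[paste0(pre, "ln2g")]], ln2_b = p[[paste0(pre, "ln2b")]],
         W1 = p[[paste0(pre, "W1")]], b1 = p[[paste0(pre, "b1")]],
         W2 = p[[paste0(pre, "W2")]], b2 = p[[paste0(pre, "b2")]])
  })
  structure(list(
    E = p$E, cls = p$cls,
    Epos = positional_encoding(cfg$n_seq + 1, cfg$D),
    blocks = blocks, lnf_g = p$lnfg, lnf_b = p$lnfb,
    head_W = p$headW, head_b = p$headb,
    D = cfg$D, n_heads = cfg$t_heads, L = cfg$L, n_tokens = cfg$n_seq,
    dropout_rate = cfg$dropout
  ), class = "transformer_params")
}
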