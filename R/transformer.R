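#' Sinusoidal positional encoding table
#'
#' Standard fixed (non-trainable) scheme with base 10000:
#' `PE[pos, 2i] = sin(pos / 10000^(2i/D))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/D))`, positions counted from 0
#' (row 1 of the returned matrix is position 0, the class token).
#'
#' @param n_positions number of positions (rows).
#' @param D embedding dimension (must be even).
#' @return `n_positions` x `D` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(n_positions, D) {
  if (D %% 2 != 0)
    gf_stop("gatformer_parameter_error", "embedding dimension D must be even")
  pos <- seq_len(n_positions) - 1
  i <- seq_len(D / 2) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / D))
  pe <- matrix(0, n_positions, D)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

#' Initialize the temporal (Transformer) encoder and classification head
#'
#' @param input_dim flattened slice length (`mu1 * mu2`, i.e. channels times
#'   per-window feature dimension).
#' @param n_tokens number of slices N per classification sample; the token
#'   sequence has length N + 1 including the class token.
#' @param D embedding dimension (default 128; divisible by `n_heads`).
#' @param n_heads self-attention heads per block (default 4).
#' @param mlp_hidden width of the feed-forward hidden layer (default `4 * D`).
#' @param L number of stacked encoder blocks (default 4).
#' @param dropout_rate dropout used after token embedding and inside the MLP.
#' @return a `transformer_params` list: linear slice projection `E`, learned
#'   class token `cls`, fixed sinusoidal table `Epos`, `L` encoder blocks
#'   (each with LayerNorm affines, fused QKV and output projections, and a
#'   two-layer GELU MLP) and the final LayerNorm + linear softmax head.
#' @export
transformer_params <- function(input_dim, n_tokens, D = 128, n_heads = 4,
                               mlp_hidden = 4 * D, L = 4, dropout_rate = 0.5) {
  if (D %% n_heads != 0)
    gf_stop("gatformer_parameter_error", "D must be divisible by n_heads")
  block <- function() list(
    ln1_g = rep(1, D), ln1_b = rep(0, D),
    Wqkv = xavier_uniform(D, 3 * D), bqkv = rep(0, 3 * D),
    Wo = xavier_uniform(D, D), bo = rep(0, D),
    ln2_g = rep(1, D), ln2_b = rep(0, D),
    W1 = xavier_uniform(D, mlp_hidden), b1 = rep(0, mlp_hidden),
    W2 = xavier_uniform(mlp_hidden, D), b2 = rep(0, D)
  )
  structure(list(
    E = xavier_uniform(input_dim, D),
    cls = rnorm(D, sd = 0.02),
    Epos = positional_encoding(n_tokens + 1, D),
    blocks = lapply(seq_len(L), function(l) block()),
    lnf_g = rep(1, D), lnf_b = rep(0, D),
    head_W = xavier_uniform(D, 2), head_b = rep(0, 2),
    D = D, n_heads = n_heads, L = L, n_tokens = n_tokens,
    dropout_rate = dropout_rate
  ), class = "transformer_params")
}

#' Embed a sequence of feature maps as Transformer tokens
#'
#' Each of the N feature maps (one per 1-s window) is flattened
#' (column-major) to a slice vector, projected to dimension D by the linear
#' map `E`, the learned class token is prepended at position 0, and the
#' positional table is added row-wise.
#'
#' @param maps list of N numeric matrices of identical shape
#'   (channels x features).
#' @param params a [transformer_params()] list.
#' @return `(N + 1) x D` token matrix.
#' @export
tokenize <- function(maps, params) {
  if (length(maps) < 1)
    gf_stop("gatformer_shape_error", "need at least one slice")
  dims <- vapply(maps, function(m) length(m), 1)
  if (any(dims != nrow(params$E)))
    gf_stop("gatformer_shape_error",
            "slice length %d does not match projection input %d",
            dims[which(dims != nrow(params$E))[1]], nrow(params$E))
  tok <- t(vapply(maps, function(m) drop(as.vector(m) %*% params$E),
                  numeric(ncol(params$E))))
  H <- rbind(params$cls, tok, deparse.level = 0)
  H + params$Epos[seq_len(nrow(H)), , drop = FALSE]
}

layer_norm <- function(x, g, b, eps = 1e-5) {
  m <- rowMeans(x)
  v <- rowMeans(x^2) - m^2
  ((x - m) / sqrt(v + eps)) * rep(g, each = nrow(x)) +
    rep(b, each = nrow(x))
}

gelu <- function(x) x * pnorm(x)

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

multi_head_self_attention <- function(X, block, n_heads) {
  D <- ncol(X)
  dh <- D / n_heads
  QKV <- X %*% block$Wqkv + rep(block$bqkv, each = nrow(X))
  Qm <- QKV[, seq_len(D), drop = FALSE]
  Km <- QKV[, D + seq_len(D), drop = FALSE]
  Vm <- QKV[, 2 * D + seq_len(D), drop = FALSE]
  O <- matrix(0, nrow(X), D)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    P <- row_softmax(Qm[, cols, drop = FALSE] %*%
                       t(Km[, cols, drop = FALSE]) / sqrt(dh))
    O[, cols] <- P %*% Vm[, cols, drop = FALSE]
  }
  O %*% block$Wo + rep(block$bo, each = nrow(X))
}

#' One pre-norm Transformer encoder block
#'
#' `H' = MSA(LN(H)) + H` followed by `H_out = MLP(LN(H')) + H'`: LayerNorm
#' inside each residual branch, standard scaled dot-product multi-head
#' self-attention over the tokens, and a two-layer feed-forward network with
#' GELU. With all MSA and MLP weights zero the block is an exact identity.
#'
#' @param H `(N + 1) x D` token matrix.
#' @param block one element of `transformer_params()$blocks`.
#' @param n_heads number of attention heads.
#' @param training logical; enables dropout inside the MLP.
#' @param dropout_rate dropout rate when training.
#' @return transformed token matrix of the same shape.
#' @export
encoder_block <- function(H, block, n_heads = 4, training = FALSE,
                          dropout_rate = 0.5) {
  H1 <- H + multi_head_self_attention(
    layer_norm(H, block$ln1_g, block$ln1_b), block, n_heads)
  A <- layer_norm(H1, block$ln2_g, block$ln2_b) %*% block$W1 +
    rep(block$b1, each = nrow(H1))
  G <- gelu(A)
  if (training)
    G <- G * matrix(dropout_mask(length(G), dropout_rate), nrow(G))
  H1 + G %*% block$W2 + rep(block$b2, each = nrow(H1))
}

#' Classify a sequence of spatial feature maps
#'
#' Tokenize, run the L encoder blocks, take the class token (position 0)
#' through the final LayerNorm and linear map, and apply softmax. The two
#' outputs are nonnegative and sum to 1.
#'
#' @param maps list of N feature maps (channels x features), one per window.
#' @param params a [transformer_params()] list.
#' @param training logical; enables dropout.
#' @return named numeric vector `c(p_seizure, p_normal)`.
#' @export
classify_sequence <- function(maps, params, training = FALSE) {
  H <- tokenize(maps, params)
  if (training)
    H <- H * matrix(dropout_mask(length(H), params$dropout_rate), nrow(H))
  for (block in params$blocks)
    H <- encoder_block(H, block, params$n_heads, training, params$dropout_rate)
  h0 <- layer_norm(H[1, , drop = FALSE], params$lnf_g, params$lnf_b)
  z <- drop(h0 %*% params$head_W) + params$head_b
  e <- exp(z - max(z))
  p <- e / sum(e)
  c(p_seizure = p[2], p_normal = p[1])
}
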