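# Elementwise nonlinearities shared by the reference path; the compiled
# training engine mirrors these definitions exactly.
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
gat_activation <- function(x, name) {
  switch(name,
    elu = elu(x),
    relu = pmax(x, 0),
    identity = x,
    gf_stop("gatformer_parameter_error", "unknown activation '%s'", name))
}

xavier_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize one graph-attention layer
#'
#' Per head `q` the layer holds a shared linear map `W_q` (input features to
#' `f_out`) and an attention vector `a_q` of length `2 * f_out` acting on the
#' concatenation of the two mapped node features. Initialization is
#' Xavier-uniform under the caller's RNG state.
#'
#' @param f_in,f_out input and output feature dimension per head.
#' @param n_heads number of attention heads (default 8).
#' @param negative_slope LeakyReLU slope used on raw attention scores.
#' @param activation output nonlinearity applied after head averaging:
#'   `"elu"` (default), `"relu"` or `"identity"`.
#' @return a `gat_layer_params` list.
#' @export
gat_layer_params <- function(f_in, f_out, n_heads = 8, negative_slope = 0.2,
                             activation = "elu") {
  structure(list(
    W = lapply(seq_len(n_heads), function(q) xavier_uniform(f_in, f_out)),
    a = lapply(seq_len(n_heads), function(q) drop(xavier_uniform(2 * f_out, 1))),
    n_heads = n_heads, negative_slope = negative_slope,
    activation = activation
  ), class = "gat_layer_params")
}

#' Attention coefficients of one head on one graph
#'
#' Raw scores are `e_ij = LeakyReLU(a^T [W h_i || W h_j])` for neighbors
#' `j` of `i` (with `a = [a1; a2]` this is `a1 . W h_i + a2 . W h_j`), and
#' the coefficients are the softmax of `e_i.` over the neighborhood of `i`
#' (numerically stabilized by subtracting the per-row maximum). Non-edges get
#' coefficient 0; every row sums to 1.
#'
#' @param h node feature matrix, nodes x features.
#' @param graph a `channel_graph` (only `adjacency` is used).
#' @param W linear map, features x f_out.
#' @param a attention vector of length `2 * f_out`.
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @return dense M x M matrix of attention coefficients.
#' @export
gat_attention <- function(h, graph, W, a, negative_slope = 0.2) {
  M <- nrow(h)
  f_out <- ncol(W)
  if (length(a) != 2 * f_out)
    gf_stop("gatformer_shape_error", "attention vector must have length 2*f_out")
  A <- graph$adjacency
  if (any(rowSums(A) == 0))
    gf_stop("gatformer_graph_error", "empty neighborhood (missing self-loops?)")
  Z <- h %*% W
  s1 <- drop(Z %*% a[seq_len(f_out)])
  s2 <- drop(Z %*% a[f_out + seq_len(f_out)])
  E <- leaky_relu(outer(s1, rep(1, M)) + outer(rep(1, M), s2), negative_slope)
  E[A == 0] <- -Inf
  E <- E - apply(E, 1, max)
  alpha <- exp(E)
  alpha[A == 0] <- 0
  alpha / rowSums(alpha)
}

#' One multi-head graph-attention layer
#'
#' Computes `act( (1/Q) * sum_q alpha_q (h W_q) )`: each head aggregates the
#' linearly mapped neighbor features with its own attention coefficients,
#' heads are averaged (not concatenated), and the nonlinearity is applied to
#' the average.
#'
#' @param h node feature matrix, nodes x features.
#' @param graph a `channel_graph`.
#' @param params a [gat_layer_params()] list.
#' @return new node feature matrix, nodes x f_out.
#' @export
gat_layer <- function(h, graph, params) {
  Q <- params$n_heads
  acc <- 0
  for (q in seq_len(Q)) {
    alpha <- gat_attention(h, graph, params$W[[q]], params$a[[q]],
                           params$negative_slope)
    acc <- acc + alpha %*% (h %*% params$W[[q]])
  }
  gat_activation(acc / Q, params$activation)
}

#' Initialize the two-layer graph-attention encoder
#'
#' @param f_in input feature dimension (samples per window).
#' @param f_hidden,f_out per-head output dimensions of layers 1 and 2.
#' @param n_heads heads per layer (default 8).
#' @param dropout_rate dropout applied to each layer's output during training.
#' @param ... passed to [gat_layer_params()].
#' @return a `gat_encoder_params` list.
#' @export
gat_encoder_params <- function(f_in, f_hidden = 64, f_out = 64, n_heads = 8,
                               dropout_rate = 0.5, ...) {
  structure(list(
    layer1 = gat_layer_params(f_in, f_hidden, n_heads, ...),
    layer2 = gat_layer_params(f_hidden, f_out, n_heads, ...),
    dropout_rate = dropout_rate
  ), class = "gat_encoder_params")
}

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (runif(n) >= rate) / (1 - rate)
}

#' Two-layer spatial encoder over a window's channel graph
#'
#' Applies [gat_layer()] twice (dropout on each layer's output when
#' `training = TRUE`), producing the spatially aggregated feature map that
#' the temporal encoder consumes. Inference (`training = FALSE`) is
#' deterministic.
#'
#' @param h node feature matrix (window samples), nodes x features.
#' @param graph the `channel_graph` built from the same window.
#' @param params a [gat_encoder_params()] list.
#' @param training logical; enables dropout.
#' @return encoded node features, nodes x f_out.
#' @export
gat_encoder <- function(h, graph, params, training = FALSE) {
  h1 <- gat_layer(h, graph, params$layer1)
  if (training)
    h1 <- h1 * matrix(dropout_mask(length(h1), params$dropout_rate), nrow(h1))
  h2 <- gat_layer(h1, graph, params$layer2)
  if (training)
    h2 <- h2 * matrix(dropout_mask(length(h2), params$dropout_rate), nrow(h2))
  h2
}
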