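# Shared fixtures, all generated in code at test time.

# small annotated subject: 60 s, 8 channels, ~2 seizures
tiny_sim_cfg <- function(seed = 1L, seizure_rate = 2, ...) {
  sim_config(n_channels = 8, duration_s = 60, fs = 64,
             seizure_rate = seizure_rate, seizure_len_s = c(6, 10),
             osc_freq_hz = 4, seed = seed, ...)
}

tiny_record <- function(seed = 1L, ...) make_subject(tiny_sim_cfg(seed, ...))

# a window set with both classes, ready for model fitting
tiny_ws <- function(seed = 1L) segment_windows(tiny_record(seed))

# a small but complete model configuration that trains in seconds
tiny_model_cfg <- function(...) {
  args <- list(n_seq = 4, gat_hidden = 4, gat_out = 4, gat_heads = 2,
               D = 8, t_heads = 2, mlp_hidden = 16, L = 2,
               epochs = 2, batch_size = 32, n_folds = 3)
  over <- list(...)
  do.call(gatformer_config, c(over, args[setdiff(names(args), names(over))]))
}

# random symmetric binary adjacency with self-loops
random_adjacency <- function(M, density = 0.4) {
  A <- matrix(rbinom(M * M, 1, density), M)
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 1
  A
}

random_graph <- function(M, F = 6, density = 0.4) {
  list(adjacency = random_adjacency(M, density),
       node_features = matrix(rnorm(M * F), M, F))
}

# channels whose sample correlation matrix equals `R` exactly
channels_with_correlation <- function(R, n = 2000) {
  M <- nrow(R)
  z <- matrix(rnorm(M * n), M, n)
  z <- z - rowMeans(z)
  # orthonormalize rows, then color with the target correlation
  z <- t(qr.Q(qr(t(z))))[seq_len(M), , drop = FALSE]
  t(chol(R)) %*% z
}
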