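# Independent brute-force oracles, deliberately written differently from the
# package implementations they check.

# textbook covariance / sd Pearson
oracle_pearson <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  cxy / (sx * sy)
}

# dense attention oracle: mask non-edges with -Inf before a full softmax
oracle_attention <- function(h, A, W, a, slope = 0.2) {
  M <- nrow(h)
  Z <- h %*% W
  f <- ncol(W)
  E <- matrix(-Inf, M, M)
  for (i in 1:M) for (j in 1:M) if (A[i, j] == 1) {
    s <- sum(a * c(Z[i, ], Z[j, ]))
    E[i, j] <- if (s > 0) s else slope * s
  }
  t(apply(E, 1, function(r) {
    e <- exp(r - max(r))
    e[!is.finite(e)] <- 0
    e / sum(e)
  }))
}

# triple-loop multi-head GAT layer (Eq-by-Eq, no vectorization)
oracle_gat_layer <- function(h, A, params) {
  M <- nrow(h)
  fo <- ncol(params$W[[1]])
  acc <- matrix(0, M, fo)
  for (q in seq_len(params$n_heads)) {
    alpha <- oracle_attention(h, A, params$W[[q]], params$a[[q]],
                              params$negative_slope)
    Z <- h %*% params$W[[q]]
    for (i in 1:M) for (j in 1:M) if (A[i, j] == 1)
      acc[i, ] <- acc[i, ] + alpha[i, j] * Z[j, ]
  }
  out <- acc / params$n_heads
  switch(params$activation,
         elu = ifelse(out > 0, out, exp(out) - 1),
         relu = pmax(out, 0),
         identity = out)
}

# loop-based pre-norm encoder block with per-head scaled dot-product MSA
oracle_encoder_block <- function(H, block, n_heads) {
  ln <- function(X, g, b) {
    t(apply(X, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * g + b
    }))
  }
  n <- nrow(H); D <- ncol(H); dh <- D / n_heads
  Y <- ln(H, block$ln1_g, block$ln1_b)
  QKV <- Y %*% block$Wqkv
  for (i in 1:n) QKV[i, ] <- QKV[i, ] + block$bqkv
  O <- matrix(0, n, D)
  for (h in 1:n_heads) {
    cols <- (h - 1) * dh + 1:dh
    Qh <- QKV[, cols, drop = FALSE]
    Kh <- QKV[, D + cols, drop = FALSE]
    Vh <- QKV[, 2 * D + cols, drop = FALSE]
    for (i in 1:n) {
      s <- numeric(n)
      for (j in 1:n) s[j] <- sum(Qh[i, ] * Kh[j, ]) / sqrt(dh)
      w <- exp(s - max(s)); w <- w / sum(w)
      for (j in 1:n) O[i, cols] <- O[i, cols] + w[j] * Vh[j, ]
    }
  }
  att <- O %*% block$Wo
  for (i in 1:n) att[i, ] <- att[i, ] + block$bo
  H1 <- H + att
  Y2 <- ln(H1, block$ln2_g, block$ln2_b)
  A <- Y2 %*% block$W1
  for (i in 1:n) A[i, ] <- A[i, ] + block$b1
  G <- A * pnorm(A)
  out <- G %*% block$W2
  for (i in 1:n) out[i, ] <- out[i, ] + block$b2
  H1 + out
}

# pairwise concordance AUC (ties count one half)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
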