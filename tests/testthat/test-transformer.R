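test_that("sinusoidal positional encodings follow the closed form", {
  pe <- positional_encoding(5, 8)
  expect_equal(pe[1, seq(1, 7, 2)], rep(0, 4)) # sin 0
  expect_equal(pe[1, seq(2, 8, 2)], rep(1, 4)) # cos 0
  expect_equal(pe[2, 1], sin(1))
  expect_equal(pe[2, 2], cos(1))
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 8)))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(4, 7), class = "gatformer_parameter_error")
})

test_that("tokenization prepends the class token and adds positions", {
  set.seed(1)
  tp <- transformer_params(input_dim = 12, n_tokens = 3, D = 8, n_heads = 2,
                           mlp_hidden = 16, L = 1)
  maps <- lapply(1:3, function(i) matrix(rnorm(12), 4, 3))
  H <- tokenize(maps, tp)
  expect_identical(dim(H), c(4L, 8L))
  expect_equal(nrow(tokenize(maps[1], tp)), 2) # N = 1 gives class + slice
  # zero projection and class token leave only the positional table
  tp0 <- tp
  tp0$E <- matrix(0, 12, 8)
  tp0$cls <- rep(0, 8)
  expect_equal(tokenize(maps, tp0), tp$Epos[1:4, ])
  # independent loop oracle: flatten -> project -> prepend -> add
  oracle <- rbind(tp$cls, t(sapply(maps, function(m) {
    v <- numeric(12)
    for (j in 1:3) for (i in 1:4) v[(j - 1) * 4 + i] <- m[i, j]
    colSums(v * tp$E)
  }))) + tp$Epos[1:4, ]
  expect_equal(unname(H), unname(oracle), tolerance = 1e-12)
  expect_error(tokenize(list(matrix(0, 2, 2)), tp),
               class = "gatformer_shape_error")
})

test_that("encoder blocks with zeroed sub-modules are exact identities", {
  set.seed(2)
  tp <- transformer_params(input_dim = 6, n_tokens = 3, D = 8, n_heads = 2,
                           mlp_hidden = 12, L = 3)
  H <- matrix(rnorm(4 * 8), 4)
  for (b in seq_along(tp$blocks)) {
    tp$blocks[[b]]$Wqkv[] <- 0; tp$blocks[[b]]$bqkv[] <- 0
    tp$blocks[[b]]$Wo[] <- 0; tp$blocks[[b]]$bo[] <- 0
    tp$blocks[[b]]$W1[] <- 0; tp$blocks[[b]]$b1[] <- 0
    tp$blocks[[b]]$W2[] <- 0; tp$blocks[[b]]$b2[] <- 0
  }
  out <- H
  for (b in tp$blocks) out <- encoder_block(out, b, n_heads = 2)
  expect_equal(out, H) # residual pass-through at every depth
})

test_that("a single token attends only to itself", {
  set.seed(3)
  tp <- transformer_params(input_dim = 4, n_tokens = 1, D = 6, n_heads = 3,
                           mlp_hidden = 8, L = 1)
  b <- tp$blocks[[1]]
  H <- matrix(rnorm(6), 1)
  # with one token, softmax weight is 1, so MSA(LN(H)) = LN(H) Wv Wo + biases
  Y <- gatformer:::layer_norm(H, b$ln1_g, b$ln1_b)
  V <- Y %*% b$Wqkv[, 13:18] + b$bqkv[13:18]
  msa <- V %*% b$Wo + b$bo
  H1 <- H + msa
  Y2 <- gatformer:::layer_norm(H1, b$ln2_g, b$ln2_b)
  mlp <- gatformer:::gelu(Y2 %*% b$W1 + b$b1) %*% b$W2 + b$b2
  expect_equal(encoder_block(H, b, n_heads = 3), H1 + mlp, tolerance = 1e-12)
})

test_that("encoder blocks match a loop-based attention oracle", {
  set.seed(4)
  for (i in 1:20) {
    D <- 8
    tp <- transformer_params(input_dim = 4, n_tokens = 3, D = D,
                             n_heads = sample(c(1, 2, 4), 1),
                             mlp_hidden = 10, L = 1)
    H <- matrix(rnorm(4 * D), 4)
    expect_equal(encoder_block(H, tp$blocks[[1]], tp$n_heads),
                 oracle_encoder_block(H, tp$blocks[[1]], tp$n_heads),
                 tolerance = 1e-10)
  }
})

test_that("classification outputs are a deterministic probability pair", {
  set.seed(5)
  tp <- transformer_params(input_dim = 12, n_tokens = 4, D = 8, n_heads = 2,
                           mlp_hidden = 16, L = 2)
  maps <- lapply(1:4, function(i) matrix(rnorm(12), 3, 4))
  p <- classify_sequence(maps, tp)
  expect_named(p, c("p_seizure", "p_normal"))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-7)
  expect_identical(p, classify_sequence(maps, tp))
  # softmax normalization holds for many random heads
  set.seed(6)
  z <- matrix(rnorm(2e4), ncol = 2) * 10
  ps <- t(apply(z, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_true(all(abs(rowSums(ps) - 1) < 1e-7))
})

test_that("permuting slices with their positional rows leaves logits unchanged", {
  set.seed(7)
  tp <- transformer_params(input_dim = 10, n_tokens = 4, D = 8, n_heads = 2,
                           mlp_hidden = 16, L = 2)
  maps <- lapply(1:4, function(i) matrix(rnorm(10), 5, 2))
  perm <- c(3, 1, 4, 2)
  tp2 <- tp
  tp2$Epos[2:5, ] <- tp$Epos[1 + perm, ]
  expect_equal(classify_sequence(maps[perm], tp2),
               classify_sequence(maps, tp), tolerance = 1e-12)
})
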