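engine_fixture <- function(M = 4, F = 12, K = 14, seed = 11) {
  set.seed(seed)
  Xbank <- array(rnorm(M * F * K), c(M, F, K))
  Abank <- array(0, c(M, M, K))
  for (k in seq_len(K)) Abank[, , k] <- random_adjacency(M)
  list(X = Xbank, A = Abank, mu = rnorm(M), sd = runif(M, 0.5, 2))
}

test_that("the compiled forward pass equals the plain-R reference model", {
  gf <- asNamespace("gatformer")
  fx <- engine_fixture()
  cfg <- tiny_model_cfg(dropout = 0.5) # inference path ignores dropout
  seq_idx <- rbind(1:4, 5:8, 9:12)
  for (mode in c("combined", "transformer_only")) {
    cfg$mode <- mode
    params <- init_model_params(cfg, 4, 12, seed = 21)
    pC <- gf$engine_predict(params, fx$X, fx$A, seq_idx, fx$mu, fx$sd, cfg)
    tp <- gf$params_to_transformer(params, cfg)
    enc <- if (mode == "combined") gf$params_to_gat_encoder(params, cfg)
    pR <- vapply(seq_len(nrow(seq_idx)), function(b) {
      maps <- lapply(seq_idx[b, ], function(k) {
        h <- (fx$X[, , k] - fx$mu) / fx$sd
        if (mode == "combined")
          gat_encoder(h, list(adjacency = fx$A[, , k]), enc)
        else h
      })
      classify_sequence(maps, tp)[["p_seizure"]]
    }, 1)
    expect_equal(pC, pR, tolerance = 1e-12, info = mode)
  }
})

test_that("analytic gradients match finite differences in every mode", {
  gf <- asNamespace("gatformer")
  fx <- engine_fixture(seed = 13)
  seq_idx <- rbind(1:4, 6:9, 10:13)
  y <- c(1L, 0L, 1L)
  cfg <- tiny_model_cfg(dropout = 0) # deterministic loss for differencing
  set.seed(5)
  for (mode in c("combined", "gat_only", "transformer_only")) {
    cfg$mode <- mode
    params <- init_model_params(cfg, 4, 12, seed = 31)
    ec <- gf$engine_cfg(cfg, training = FALSE, compute_grads = TRUE, 1)
    out <- gf$.engine_run(params, fx$X, fx$A, seq_idx, fx$mu, fx$sd, y, ec)
    ec0 <- gf$engine_cfg(cfg, training = FALSE, compute_grads = FALSE, 1)
    lossfun <- function(p)
      gf$.engine_run(p, fx$X, fx$A, seq_idx, fx$mu, fx$sd, y, ec0)$loss
    for (nm in names(out$grads)) {
      g <- out$grads[[nm]]
      dim(g) <- dim(params[[nm]])
      for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        h <- 1e-5
        up <- params; up[[nm]][i] <- up[[nm]][i] + h
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
        fd <- (lossfun(up) - lossfun(dn)) / (2 * h)
        expect_equal(g[i], fd, tolerance = 1e-4,
                     info = sprintf("%s %s[%d]", mode, nm, i))
      }
    }
  }
})

test_that("sequence construction takes the tie-favouring majority label", {
  sq <- build_sequences(c(0, 0, 1, 1, 1, 0), n_seq = 4)
  expect_equal(dim(sq$idx), c(3L, 4L))
  expect_equal(sq$idx[2, ], 2:5)
  expect_equal(sq$labels, c(1L, 1L, 1L)) # 2/4 ties count as seizure
  sq1 <- build_sequences(c(0, 0, 0, 1), n_seq = 4)
  expect_equal(sq1$labels, 0L) # 1/4 below majority
  expect_error(build_sequences(c(0, 1), 4), class = "gatformer_shape_error")
})

test_that("stratified folds are disjoint, exhaustive and evenly stratified", {
  labels <- rep(c(1, 0), c(100, 100))
  folds <- stratified_kfold(labels, 10, seed = 1)
  expect_equal(sort(unlist(folds)), 1:200)
  for (f in folds) {
    expect_equal(sum(labels[f] == 1), 10)
    expect_equal(sum(labels[f] == 0), 10)
  }
  # 95 + 100: per-fold positive counts differ by at most one
  lab2 <- rep(c(1, 0), c(95, 100))
  for (method in c("block", "random")) {
    folds2 <- stratified_kfold(lab2, 10, seed = 2, method = method)
    expect_equal(sort(unlist(folds2)), 1:195)
    pos <- vapply(folds2, function(f) sum(lab2[f] == 1), 1)
    expect_lte(diff(range(pos)), 1)
  }
  expect_identical(stratified_kfold(lab2, 10, seed = 3),
                   stratified_kfold(lab2, 10, seed = 3))
  expect_error(stratified_kfold(rep(c(1, 0), c(5, 100)), 10),
               class = "gatformer_stratification_error")
})

test_that("training is seed-deterministic and minimises the focal loss", {
  gf <- asNamespace("gatformer")
  ws <- tiny_ws(seed = 6)
  cfg <- tiny_model_cfg(epochs = 3, seed = 2)
  m1 <- gatformer(ws, cfg)
  expect_length(m1$loss_history, 3)
  expect_lt(m1$loss_history[3], m1$loss_history[1])
  m2 <- gatformer(ws, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_history, m2$loss_history)
  # prediction is deterministic and probabilistic
  p <- predict(m1, ws)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(m2, ws))
})

test_that("a trained combined model clearly beats chance on separable data", {
  rec <- make_subject(sim_config(n_channels = 8, duration_s = 240, fs = 64,
                                 seizure_rate = 12, seizure_len_s = c(8, 12),
                                 seed = 8))
  ws <- segment_windows(bandpass(rec, 0.5, 28))
  cfg <- tiny_model_cfg(epochs = 15, gat_hidden = 8, gat_out = 8, D = 16,
                        mlp_hidden = 32, seed = 3)
  m <- gatformer(ws, cfg)
  truth <- predict(m, ws, type = "sequence_labels")
  acc <- mean(predict(m, ws, type = "class") == truth)
  constant <- max(mean(truth), 1 - mean(truth))
  expect_gte(acc, constant + 0.3) # at least 30 points over any constant rule
  expect_gt(acc, untrained_accuracy(ws, cfg) + 0.2)
})

test_that("cross-validation never leaks test data into fitting decisions", {
  ws <- tiny_ws(seed = 9)
  cfg <- tiny_model_cfg(epochs = 1, n_folds = 3, seed = 4)
  cv <- gatformer_cv(ws, cfg)
  expect_s3_class(cv, "gatformer_cv")
  expect_length(cv$report$folds, 3)
  sq <- build_sequences(ws$labels, cfg$n_seq)
  for (f in seq_along(cv$folds)) {
    test_idx <- cv$folds[[f]]
    fr <- cv$report$folds[[f]]
    # test folds are scored raw: one score per untouched test sample
    expect_length(fr$scores, length(test_idx))
    expect_identical(fr$truth, sq$labels[test_idx])
    counts <- unlist(fr$counts, use.names = FALSE)
    expect_equal(sum(counts), length(test_idx))
    # z-score statistics derive from training windows only
    train_idx <- setdiff(seq_along(sq$labels), test_idx)
    stats <- gatformer:::zscore_fit_subset(
      ws, unique(as.vector(sq$idx[train_idx, ])))
    all_stats <- zscore_fit(ws)
    expect_false(isTRUE(all.equal(stats$mean, all_stats$mean)))
  }
  expect_true(all(colnames(cv$report$per_fold) ==
                    c("accuracy", "sensitivity", "specificity", "f1", "auc")))
})

test_that("ablation modes run end to end and report the same interface", {
  ws <- tiny_ws(seed = 10)
  for (mode in c("gat_only", "transformer_only")) {
    cfg <- tiny_model_cfg(epochs = 1, n_folds = 3, seed = 5, mode = mode)
    cv <- gatformer_cv(ws, cfg)
    expect_true(all(cv$report$mean >= 0 & cv$report$mean <= 1))
  }
})
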