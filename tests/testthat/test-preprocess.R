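test_that("montage selection reorders, canonicalizes and reports missing channels", {
  rec <- tiny_record(seed = 1)
  expect_identical(select_montage(rec, rec$channel_labels)$data, rec$data)
  rev_rec <- select_montage(rec, rev(rec$channel_labels))
  expect_identical(rev_rec$data, rec$data[rev(seq_len(nrow(rec$data))), ])
  # whitespace / case are canonicalized before matching
  sloppy <- paste0(" ", tolower(rec$channel_labels[1]), " ")
  expect_identical(select_montage(rec, sloppy)$data[1, ], rec$data[1, ])
  err <- tryCatch(select_montage(rec, "FP1-F7"), error = identity)
  expect_s3_class(err, "gatformer_montage_error")
  expect_match(conditionMessage(err), "FP1-F7")
})

test_that("the built-in montage presets match their recordings", {
  labels <- montage_preset("chbmit16")
  expect_length(labels, 16)
  expect_length(montage_preset("tuh20"), 20)
  # a record carrying the 16 standard bipolar channels in scrambled order
  data <- matrix(rnorm(16 * 64), 16)
  rec <- eeg_record(data[c(16:1), , drop = FALSE], 64, rev(labels))
  out <- select_montage(rec, "chbmit16")
  expect_identical(out$channel_labels, labels)
  expect_equal(nrow(out$data), 16)
  expect_identical(out$data[1, ], data[1, ]) # back in preset order
})

test_that("bandpass attenuates out-of-band and passes in-band tones", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  mk <- function(f) eeg_record(matrix(sin(2 * pi * f * t), 1), fs, "CH1-REF")
  out60 <- bandpass(mk(60), 0.5, 48)
  expect_lt(rms(out60$data) / rms(mk(60)$data), 0.05)
  out10 <- bandpass(mk(10), 0.5, 48)
  expect_lt(abs(rms(out10$data) / rms(mk(10)$data) - 1), 0.1)
  zero <- bandpass(eeg_record(matrix(0, 2, fs), fs, c("A-B", "C-D")), 0.5, 48)
  expect_true(all(zero$data == 0))
  expect_error(bandpass(mk(10), 0.5, 200), class = "gatformer_parameter_error")
})

test_that("window counts follow the sliding-window formula", {
  rec_of <- function(T_s, fs = 32) {
    eeg_record(matrix(rnorm(2 * round(T_s * fs)), 2), fs, c("A-B", "C-D"))
  }
  expect_equal(n_windows(segment_windows(rec_of(60), 1, 0.5)), 119)
  expect_equal(n_windows(segment_windows(rec_of(1), 1, 0.5)), 1)
  expect_equal(n_windows(segment_windows(rec_of(2), 1, 0.5)), 3)
  expect_error(segment_windows(rec_of(0.5), 1, 0.5),
               class = "gatformer_segmentation_error")
  # property: K matches brute-force start enumeration
  set.seed(42)
  for (i in 1:25) {
    T_s <- round(runif(1, 2, 30), 2)
    w <- sample(c(0.5, 1, 2), 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    if (T_s < w) next
    step <- w * (1 - ov)
    brute <- sum(seq(0, T_s, by = step) + w <= T_s + 1e-9)
    expect_equal(n_windows(segment_windows(rec_of(T_s), w, ov)), brute,
                 info = sprintf("T=%g w=%g ov=%g", T_s, w, ov))
  }
})

test_that("majority-overlap labelling is exact at the boundary and order-invariant", {
  rec <- eeg_record(matrix(rnorm(2 * 12 * 16), 2), 16, c("A-B", "C-D"))
  ws <- segment_windows(rec, 1, 0)
  lab <- function(iv) label_windows(ws, iv)$labels
  expect_equal(lab(rbind(c(2, 3)))[3], 1)          # fully inside
  expect_equal(lab(rbind(c(2, 3)))[5], 0)          # zero overlap
  expect_equal(lab(rbind(c(1.6, 10)))[2], 0)       # window [1,2): overlap 0.4
  expect_equal(lab(rbind(c(1.5, 10)))[2], 1)       # exactly 50%: seizure
  iv <- rbind(c(0.2, 1.4), c(3.1, 4.0), c(6, 7.5))
  expect_identical(lab(iv), lab(iv[c(2, 3, 1), ]))
})

test_that("1:1 balancing oversamples only the minority with whole-window copies", {
  ws <- tiny_ws(seed = 2)
  n1 <- sum(ws$labels == 1); n0 <- sum(ws$labels == 0)
  expect_true(n1 > 0 && n0 > 0 && n1 != n0)
  bal <- balance_1to1(ws, seed = 9)
  expect_equal(sum(bal$labels == 1), sum(bal$labels == 0))
  expect_equal(n_windows(bal), 2 * max(n0, n1))
  # originals are untouched and lead; extras duplicate existing minority starts
  expect_identical(bal$starts[seq_len(n_windows(ws))], ws$starts)
  extra <- bal$starts[-seq_len(n_windows(ws))]
  minority <- if (n1 < n0) 1L else 0L
  expect_true(all(extra %in% ws$starts[ws$labels == minority]))
  expect_identical(balance_1to1(ws, seed = 9)$starts, bal$starts)
  # already balanced input is returned unchanged
  idx <- c(which(ws$labels == 1)[1:5], which(ws$labels == 0)[1:5])
  even <- window_set(ws$data[, , idx], ws$labels[idx], ws$starts[idx],
                     ws$fs, ws$channel_labels)
  expect_identical(balance_1to1(even, 1)$starts, even$starts)
  only1 <- window_set(ws$data[, , ws$labels == 1],
                      ws$labels[ws$labels == 1],
                      ws$starts[ws$labels == 1], ws$fs, ws$channel_labels)
  expect_error(balance_1to1(only1, 1), class = "gatformer_balance_error")
})

test_that("z-scoring normalizes the fitted set and floors constant channels", {
  ws <- tiny_ws(seed = 3)
  stats <- zscore_fit(ws)
  out <- zscore_apply(ws, stats)
  flat <- out$data
  dim(flat) <- c(dim(out$data)[1], prod(dim(out$data)[2:3]))
  expect_equal(rowMeans(flat), rep(0, nrow(flat)), tolerance = 1e-10)
  expect_equal(apply(flat, 1, sd), rep(1, nrow(flat)), tolerance = 1e-3)
  # constant channel maps to zeros
  cws <- ws
  cws$data[1, , ] <- 5
  cstats <- zscore_fit(cws)
  expect_equal(cstats$sd[1], 1e-8)
  expect_true(all(zscore_apply(cws, cstats)$data[1, , ] == 0))
  # stats fitted on one half generally do not center the other half
  half <- seq_len(n_windows(ws) %/% 2)
  s1 <- zscore_fit(window_set(ws$data[, , half], ws$labels[half],
                              ws$starts[half], ws$fs, ws$channel_labels))
  rest <- zscore_apply(ws, s1)$data[, , -half]
  expect_gt(max(abs(rowMeans(matrix(rest, dim(ws$data)[1])))), 1e-4)
})
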