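test_that("confusion counts match a loop oracle", {
  expect_equal(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  truth <- c(1, 0, 1, 0)
  cc <- confusion_counts(1 - truth, truth)
  expect_equal(cc$TP + cc$TN, 0L)
  set.seed(1)
  pred <- rbinom(200, 1, 0.4); truth <- rbinom(200, 1, 0.3)
  cc <- confusion_counts(pred, truth)
  loop <- c(0, 0, 0, 0)
  for (i in 1:200) {
    if (pred[i] == 1 && truth[i] == 1) loop[1] <- loop[1] + 1
    if (pred[i] == 1 && truth[i] == 0) loop[2] <- loop[2] + 1
    if (pred[i] == 0 && truth[i] == 0) loop[3] <- loop[3] + 1
    if (pred[i] == 0 && truth[i] == 1) loop[4] <- loop[4] + 1
  }
  expect_equal(unlist(cc, use.names = FALSE), as.integer(loop))
  expect_error(confusion_counts(1, c(1, 0)), class = "gatformer_shape_error")
})

test_that("confusion metrics reproduce hand-computed values", {
  m <- binary_metrics(list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  expect_equal(unname(m), rep(1, 4))
  m <- binary_metrics(list(TP = 8L, FN = 2L, TN = 6L, FP = 4L))
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.6)
  expect_equal(m[["f1"]], 2 * (8 / 12) * (8 / 10) / ((8 / 12) + (8 / 10)))
  expect_equal(m[["f1"]], 0.7273, tolerance = 1e-4)
  # undefined precision: F1 is 0 with a warning, never NaN
  expect_warning(m0 <- binary_metrics(list(TP = 0L, FP = 0L, TN = 5L, FN = 3L)),
                 "precision")
  expect_equal(m0[["f1"]], 0)
  expect_false(anyNA(m0))
})

test_that("accuracy sits between sensitivity and specificity for balanced classes", {
  set.seed(2)
  for (i in 1:20) {
    truth <- rep(0:1, each = 25)
    pred <- ifelse(runif(50) < 0.3, 1 - truth, truth)
    m <- binary_metrics(confusion_counts(pred, truth))
    expect_gte(m[["accuracy"]], min(m[["sensitivity"]], m[["specificity"]]))
    expect_lte(m[["accuracy"]], max(m[["sensitivity"]], m[["specificity"]]))
  }
})

test_that("rank-based AUC equals pairwise concordance and handles ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "gatformer_auc_error")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 1) # coarse grid forces ties
    expect_equal(roc_auc(scores, truth), oracle_auc(scores, truth),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(qlogis(pmin(pmax(scores, .01), .99)), truth),
                 roc_auc(pmin(pmax(scores, .01), .99), truth))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- runif(80)
  truth <- rbinom(80, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, truth), ref, tolerance = 1e-12)
})

test_that("report aggregation uses fold-order-invariant mean and population sd", {
  mk <- function(f, acc) list(fold = f, counts = NULL,
                              metrics = c(accuracy = acc, auc = 1),
                              scores = NULL, truth = NULL)
  rep2 <- aggregate_report(list(mk(1, 0.9), mk(2, 1.0)))
  expect_equal(rep2$mean[["accuracy"]], 0.95)
  expect_equal(rep2$sd[["accuracy"]], 0.05)
  rep1 <- aggregate_report(list(mk(1, 0.8)))
  expect_equal(rep1$sd[["accuracy"]], 0)
  shuffled <- aggregate_report(list(mk(2, 1.0), mk(1, 0.9)))
  expect_equal(shuffled$mean, rep2$mean)
  expect_equal(shuffled$sd, rep2$sd)
})

test_that("report writers emit one row per fold plus mean and sd", {
  mk <- function(f, acc) list(fold = f, counts = NULL,
                              metrics = c(accuracy = acc, auc = 1),
                              scores = NULL, truth = NULL)
  rep3 <- aggregate_report(lapply(1:3, function(f) mk(f, 0.8 + 0.05 * f)))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_report(rep3, csv, jsn)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$fold, c("fold01", "fold02", "fold03", "mean", "sd"))
  expect_equal(tab$accuracy[4], 90) # percentages, two decimals
  parsed <- jsonlite::read_json(jsn)
  expect_equal(parsed$mean$accuracy, 0.9, tolerance = 1e-12)
})
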