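test_that("pearson_r matches the textbook oracle and handles degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  x <- rnorm(50)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, rep(2, 50)), 0)
  expect_error(pearson_r(x, rnorm(10)), class = "gatformer_shape_error")
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30) + runif(1, -1, 1) * a
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
})

test_that("correlation_matrix is the element-wise pearson_r matrix", {
  set.seed(2)
  w <- matrix(rnorm(5 * 40), 5)
  cm <- correlation_matrix(w)
  for (i in 1:5) for (j in 1:5)
    expect_equal(cm[i, j], if (i == j) 1 else pearson_r(w[i, ], w[j, ]),
                 tolerance = 1e-12)
  # identical channels are perfectly correlated
  same <- matrix(rep(rnorm(30), 3), 3, byrow = TRUE)
  expect_equal(correlation_matrix(same), matrix(1, 3, 3))
  # independent long noise channels decorrelate
  long <- matrix(rnorm(4 * 2560), 4)
  cml <- correlation_matrix(long)
  expect_lt(max(abs(cml[upper.tri(cml)])), 0.2)
  # degenerate channel: zero correlation to others, unit diagonal
  w[2, ] <- 7
  cm2 <- correlation_matrix(w)
  expect_true(all(cm2[2, -2] == 0) && all(cm2[-2, 2] == 0))
  expect_equal(diag(cm2), rep(1, 5))
})

test_that("strength categories reproduce the published bands at all boundaries", {
  expect_equal(as.character(strength_category(0.86)), "very strong")
  expect_equal(as.character(strength_category(0.69)), "strong")
  expect_equal(as.character(strength_category(0)), "very weak or none")
  # left-closed bands; top band includes 1; sign is ignored
  got <- as.character(strength_category(c(0.2, 0.4, 0.6, 0.8, 1.0, -0.45)))
  expect_equal(got, c("weak", "moderate", "strong", "very strong",
                      "very strong", "moderate"))
  expect_equal(as.character(strength_category(0.2 - 1e-9)), "very weak or none")
  expect_error(strength_category(1.2), class = "gatformer_domain_error")
})

test_that("thresholding builds the expected adjacency on a controlled window", {
  R <- matrix(c(1, .9, .1,
                .9, 1, .5,
                .1, .5, 1), 3, 3)
  w <- channels_with_correlation(R)
  g <- build_graph(w, tau = 0.3)
  expect_equal(g$correlation, R, tolerance = 1e-8)
  expect_equal(g$adjacency, matrix(c(1, 1, 0,
                                     1, 1, 1,
                                     0, 1, 1), 3, 3))
  expect_equal(neighborhood(g, 1), c(1, 2))
})

test_that("adjacency is symmetric, binary, self-looped and monotone in tau", {
  set.seed(3)
  for (i in 1:10) {
    w <- matrix(rnorm(6 * 50), 6)
    taus <- c(0.1, 0.3, 0.6, 0.9)
    gs <- lapply(taus, function(tau) build_graph(w, tau))
    for (g in gs) {
      expect_true(all(g$adjacency %in% c(0, 1)))
      expect_identical(g$adjacency, t(g$adjacency))
      expect_equal(diag(g$adjacency), rep(1, 6))
      expect_true(all(rowSums(g$adjacency) >= 1))
    }
    for (k in seq_len(length(taus) - 1)) # edges shrink as tau grows
      expect_true(all(gs[[k + 1]]$adjacency <= gs[[k]]$adjacency))
  }
  # tau extremes
  w <- matrix(rnorm(4 * 2560), 4)
  expect_equal(build_graph(w, 0.999)$adjacency, diag(4))
  expect_true(all(build_graph(w, 1e-6)$adjacency == 1))
  # boundary |r| == tau counts as an edge
  wb <- channels_with_correlation(matrix(c(1, -.3, -.3, 1), 2), 500)
  r <- abs(correlation_matrix(wb)[1, 2])
  expect_equal(build_graph(wb, r)$adjacency, matrix(1, 2, 2))
  expect_equal(build_graph(wb, min(r + 1e-9, 0.999))$adjacency, diag(2))
})

test_that("graph dumps write inspectable edge lists", {
  g <- build_graph(matrix(rnorm(4 * 100), 4), 0.05)
  ep <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  dump_graph(g, ep, cp)
  edges <- read.csv(ep)
  expect_true(all(edges$i < edges$j))
  expect_equal(nrow(edges), (sum(g$adjacency) - 4) / 2)
  expect_equal(unname(as.matrix(read.csv(cp))), unname(g$correlation),
               tolerance = 1e-12)
})
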