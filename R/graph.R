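#' Pearson correlation coefficient
#'
#' Computed directly as covariance over the product of standard deviations.
#' If either input has zero variance the coefficient is defined as 0 (the
#' degenerate-channel convention used throughout the package).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    gf_stop("gatformer_shape_error", "pearson_r: lengths differ (%d vs %d)",
            length(x), length(y))
  if (length(x) < 2)
    gf_stop("gatformer_shape_error", "pearson_r: need length >= 2")
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) return(0)
  r <- sum(dx * dy) / sqrt(vx * vy)
  min(max(r, -1), 1)
}

#' Channel-by-channel correlation matrix of one window
#'
#' Pearson correlation between every pair of channel time series. Degenerate
#' (zero-variance) channels get correlation 0 with every other channel; the
#' diagonal is always 1.
#'
#' @param w numeric matrix, channels x samples (a window), or the `data`
#'   element of [get_window()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(w) {
  if (is.list(w)) w <- w$data
  if (nrow(w) < 2)
    gf_stop("gatformer_shape_error", "need at least 2 channels")
  sds <- apply(w, 1, sd)
  cm <- suppressWarnings(cor(t(w)))
  cm[!is.finite(cm)] <- 0
  cm[sds == 0, ] <- 0
  cm[, sds == 0] <- 0
  diag(cm) <- 1
  cm
}

#' Categorize correlation strength
#'
#' Bands on `|r|`: `[0, 0.2)` very weak or none, `[0.2, 0.4)` weak,
#' `[0.4, 0.6)` moderate, `[0.6, 0.8)` strong, `[0.8, 1]` very strong. All
#' bands are left-closed and right-open except the top band, which includes 1.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return factor with levels from "very weak or none" to "very strong".
#' @export
strength_category <- function(r) {
  if (any(abs(r) > 1 + 1e-12))
    gf_stop("gatformer_domain_error", "|r| must be <= 1")
  lv <- c("very weak or none", "weak", "moderate", "strong", "very strong")
  idx <- findInterval(pmin(abs(r), 1), c(0, 0.2, 0.4, 0.6, 0.8, 1 + 1e-9))
  factor(lv[idx], levels = lv)
}

#' Build a channel graph from one window
#'
#' Edges connect channel pairs whose absolute correlation is at least `tau`
#' (strong anticorrelation also creates an edge); self-loops are always
#' present so every neighborhood is non-empty. Node features are the raw
#' window samples.
#'
#' @param w channels x samples matrix (one window).
#' @param tau correlation threshold in `(0, 1)` (default 0.3).
#' @return an object of class `channel_graph` with elements `adjacency`
#'   (binary, symmetric, unit diagonal), `correlation` (the untruncated
#'   matrix) and `node_features` (the input window).
#' @export
build_graph <- function(w, tau = 0.3) {
  if (is.list(w)) w <- w$data
  if (!is_scalar(tau) || tau <= 0 || tau >= 1)
    gf_stop("gatformer_parameter_error", "tau must be in (0, 1)")
  cm <- correlation_matrix(w)
  adj <- (abs(cm) >= tau) * 1
  diag(adj) <- 1
  structure(list(adjacency = adj, correlation = cm, node_features = w,
                 tau = tau),
            class = "channel_graph")
}

#' Neighborhood of a node
#' @param graph a `channel_graph` (or any list with an `adjacency` element).
#' @param i node index.
#' @return integer vector of neighbors of node `i` (including itself).
#' @export
neighborhood <- function(graph, i) which(graph$adjacency[i, ] == 1)

#' @export
print.channel_graph <- function(x, ...) {
  M <- nrow(x$adjacency)
  cat(sprintf("<channel_graph> %d nodes, %d edges (tau = %g), %d features/node\n",
              M, (sum(x$adjacency) - M) / 2, x$tau, ncol(x$node_features)))
  invisible(x)
}

#' Write a graph to CSV files for inspection
#'
#' Writes the edge list (columns `i,j`, undirected pairs with `i < j`) and
#' the correlation matrix as CSV.
#'
#' @param graph a `channel_graph`.
#' @param edge_path,corr_path output paths (either may be `NULL` to skip).
#' @return invisibly, the list of written paths.
#' @export
dump_graph <- function(graph, edge_path = NULL, corr_path = NULL) {
  if (!is.null(edge_path)) {
    e <- which(upper.tri(graph$adjacency) & graph$adjacency == 1, arr.ind = TRUE)
    write.csv(data.frame(i = e[, 1], j = e[, 2]), edge_path, row.names = FALSE)
  }
  if (!is.null(corr_path))
    write.csv(as.data.frame(graph$correlation), corr_path, row.names = FALSE)
  invisible(list(edges = edge_path, correlation = corr_path))
}

# Adjacency bank for a whole window set: M x M x K binary array. Correlation
# is invariant to per-channel affine maps, so graphs may be built before or
# after z-scoring with identical results.
build_graph_bank <- function(ws, tau = 0.3) {
  d <- dim(ws$data)
  A <- array(0, c(d[1], d[1], d[3]))
  for (k in seq_len(d[3]))
    A[, , k] <- build_graph(ws$data[, , k], tau)$adjacency
  A
}
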