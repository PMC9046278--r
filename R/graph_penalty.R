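#' Construct a feature graph
#'
#' A weighted undirected graph over one dataset's features.  The adjacency
#' matrix holds nonnegative edge weights with a zero diagonal; the degree
#' matrix is `diag(rowSums(A))` and the graph Laplacian is `L = D - A`.
#' The Laplacian's quadratic form sums weighted squared differences across
#' edges, \eqn{u^T L u = \sum_{i<k} a_{ik} (u_i - u_k)^2}, which is what
#' makes it a smoothness penalty: features joined by heavy edges are pushed
#' towards similar weights.
#'
#' @param adjacency Square symmetric numeric matrix of nonnegative edge
#'   weights; the diagonal is forced to zero so self-loops never contribute.
#' @param feature_labels Optional character vector of node names.
#' @return An object of class `feature_graph` with elements `adjacency`,
#'   `degree`, `laplacian` and `feature_labels`.
#' @export
feature_graph <- function(adjacency, feature_labels = NULL) {
  A <- as.matrix(adjacency)
  storage.mode(A) <- "double"
  if (nrow(A) != ncol(A)) {
    stop("adjacency must be square", call. = FALSE)
  }
  if (any(!is.finite(A))) stop("adjacency must be finite", call. = FALSE)
  if (any(A < 0)) {
    stop("adjacency weights must be nonnegative", call. = FALSE)
  }
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  A <- (A + t(A)) / 2
  diag(A) <- 0
  if (is.null(feature_labels)) {
    feature_labels <- colnames(A)
    if (is.null(feature_labels)) {
      feature_labels <- paste0("V", seq_len(ncol(A)))
    }
  }
  dimnames(A) <- list(feature_labels, feature_labels)
  D <- diag(rowSums(A), nrow(A))
  structure(
    list(adjacency = A, degree = D, laplacian = D - A,
         feature_labels = as.character(feature_labels)),
    class = "feature_graph"
  )
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("<feature_graph: %d nodes, %d edges>\n",
              nrow(x$adjacency), sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}

#' Correlation-derived feature adjacency
#'
#' Builds the adjacency matrix from absolute pairwise Pearson correlations
#' between feature columns: higher correlation between two features gives a
#' larger edge weight.  Absolute values are used because the Laplacian
#' quadratic form requires nonnegative weights to stay positive
#' semi-definite.  Weights below `edge_threshold` are set to zero.
#'
#' @param X A `feature_matrix` or matrix with at least 3 samples.
#' @param edge_threshold Scalar in `[0, 1]`; weights strictly below it are
#'   dropped.  Default 0 keeps the fully dense graph.
#' @return A `feature_graph`.
#' @export
adjacency_from_correlation <- function(X, edge_threshold = 0) {
  X <- as_feature_matrix(X)
  v <- X$values
  if (nrow(v) < 3) {
    stop("at least 3 samples are required to estimate correlations",
         call. = FALSE)
  }
  if (!is.numeric(edge_threshold) || length(edge_threshold) != 1 ||
      edge_threshold < 0 || edge_threshold > 1) {
    stop("edge_threshold must be a scalar in [0, 1]", call. = FALSE)
  }
  sds <- apply(v, 2, stats::sd)
  const <- sds < .Machine$double.eps * 10
  if (any(const)) {
    warning(sprintf("constant column(s); their correlations set to 0: %s",
                    paste(X$feature_labels[const], collapse = ", ")),
            call. = FALSE)
  }
  p <- ncol(v)
  A <- matrix(0, p, p)
  if (p > 1 && any(!const)) {
    ok <- which(!const)
    C <- abs(stats::cor(v[, ok, drop = FALSE]))
    A[ok, ok] <- C
  }
  diag(A) <- 0
  A[A < edge_threshold] <- 0
  feature_graph(A, X$feature_labels)
}

#' Graph Laplacian of a feature graph
#'
#' Returns `L = D - A`.  `L` is symmetric positive semi-definite with zero
#' row sums.
#'
#' @param G A `feature_graph` (or a raw adjacency matrix, validated first).
#' @return The Laplacian matrix.
#' @export
laplacian <- function(G) {
  if (!inherits(G, "feature_graph")) G <- feature_graph(G)
  G$laplacian
}

#' GraphNet penalty
#'
#' Evaluates \eqn{\lambda_1 u^T M u + \gamma_1 \|u\|_1} with `M` the graph
#' Laplacian.  Setting `M = I` (via `identity_quadratic = TRUE`) recovers
#' the elastic net.
#'
#' @param u Numeric weight vector, one entry per graph node.
#' @param G A `feature_graph`.
#' @param lambda1 Nonnegative weight on the quadratic (smoothness) term.
#' @param gamma1 Nonnegative weight on the L1 (sparsity) term.
#' @param identity_quadratic If `TRUE` use `M = I` instead of the Laplacian.
#' @return Scalar penalty value.
#' @export
graphnet_penalty <- function(u, G, lambda1, gamma1,
                             identity_quadratic = FALSE) {
  if (lambda1 < 0 || gamma1 < 0) {
    stop("lambda1 and gamma1 must be nonnegative", call. = FALSE)
  }
  if (!inherits(G, "feature_graph")) G <- feature_graph(G)
  u <- as.numeric(u)
  if (length(u) != nrow(G$adjacency)) {
    stop("length(u) must equal the graph size", call. = FALSE)
  }
  M <- if (identity_quadratic) diag(length(u)) else G$laplacian
  lambda1 * drop(crossprod(u, M %*% u)) + gamma1 * sum(abs(u))
}

#' Read a feature graph from delimited text
#'
#' Square matrix with a header row of feature labels.
#' @param path File path.
#' @param sep Field separator.
#' @return A `feature_graph`.
#' @export
read_feature_graph <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  feature_graph(as.matrix(df), colnames(df))
}

#' Write a feature graph as delimited text
#'
#' @param G A `feature_graph`.
#' @param path Output path.
#' @param sep Field separator.
#' @param digits Significant digits (default 12; round-trips exactly at
#'   that precision).
#' @export
write_feature_graph <- function(G, path, sep = "\t", digits = 12) {
  if (!inherits(G, "feature_graph")) G <- feature_graph(G)
  write_feature_matrix(
    feature_matrix(G$adjacency, G$feature_labels, set_id = "graph"),
    path, sep = sep, digits = digits
  )
}
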