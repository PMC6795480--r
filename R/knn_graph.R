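#' Directed kNN graph objects
#'
#' A `knn_graph` stores, for each of `n` cells, the indices of its `k`
#' neighbors (always including the cell itself). It corresponds to a directed
#' 0/1 adjacency matrix with exactly `k` out-edges per row.
#'
#' @param idx Integer n x k matrix of neighbor indices, one row per cell.
#' @return An object of class `knn_graph`.
#' @keywords internal
new_knn_graph <- function(idx) {
  storage.mode(idx) <- "integer"
  structure(list(idx = idx, n = nrow(idx), k = ncol(idx)),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat("Directed kNN graph:", x$n, "cells, k =", x$k, "\n")
  invisible(x)
}

#' Random kNN graph initialization
#'
#' Each cell's neighbor set is itself plus `k - 1` distinct other cells drawn
#' uniformly without replacement. This is the random starting graph from which
#' the manifold reconstruction iterates.
#'
#' @param n Number of cells.
#' @param k Neighborhood size (including self); `1 <= k < n`.
#' @param seed Integer seed; identical seeds give identical graphs.
#' @return A [`knn_graph`][new_knn_graph].
#' @export
random_knn_graph <- function(n, k, seed = 0L) {
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  idx <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      others <- if (k > 1) sample(seq_len(n)[-i], k - 1) else integer(0)
      sort(c(i, others))
    }, integer(k)))
  })
  if (k == 1) idx <- matrix(seq_len(n), ncol = 1)
  new_knn_graph(idx)
}

#' Convert a kNN graph to a sparse adjacency matrix
#'
#' @param graph A `knn_graph`.
#' @return A sparse 0/1 `dgCMatrix` with row sums `k` (directed: rows are
#'   source cells).
#' @export
as_adjacency <- function(graph) {
  stopifnot(inherits(graph, "knn_graph"))
  Matrix::sparseMatrix(i = rep(seq_len(graph$n), each = graph$k),
                       j = as.vector(t(graph$idx)),
                       x = 1, dims = c(graph$n, graph$n))
}

#' Build a kNN graph from an adjacency matrix
#'
#' @param A 0/1 matrix (dense or sparse) with a constant row sum.
#' @return A `knn_graph`.
#' @export
graph_from_adjacency <- function(A) {
  A <- as(as(A, "CsparseMatrix"), "generalMatrix")
  rs <- Matrix::rowSums(A != 0)
  if (length(unique(rs)) != 1L)
    stop("adjacency rows do not share a common out-degree", call. = FALSE)
  k <- as.integer(rs[1])
  idx <- t(apply(as.matrix(A != 0), 1, which))
  if (k == 1L) idx <- matrix(as.integer(idx), ncol = 1)
  new_knn_graph(idx)
}

#' Average expression over graph neighborhoods
#'
#' Computes `C = (1/k) N E`: row i of the result is the mean expression
#' profile of cell i's neighbor set. Neighborhood averaging is what ties gene
#' dispersion to the graph's topology rather than to individual cells.
#'
#' @param graph A `knn_graph` over the same cells as `E`.
#' @param E Cells x genes matrix (log scale, nonnegative).
#' @return Cells x genes matrix of neighborhood means.
#' @export
knn_average <- function(graph, E) {
  stopifnot_matrix(E)
  if (graph$n != nrow(E))
    stop("graph and expression matrix disagree on the number of cells",
         call. = FALSE)
  C <- as.matrix(as_adjacency(graph) %*% E) / graph$k
  dimnames(C) <- dimnames(E)
  C
}

#' Rebuild the kNN graph from a distance matrix
#'
#' Each cell's neighbor set becomes itself plus the `k - 1` nearest other
#' cells; ties are broken deterministically by ascending cell index so runs
#' are reproducible.
#'
#' @param D Symmetric n x n distance matrix with zero diagonal.
#' @param k Neighborhood size (including self).
#' @return A `knn_graph`.
#' @export
update_knn <- function(D, k) {
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  idx <- t(vapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))   # stable: ties by ascending index
    ord <- ord[ord != i]
    sort(c(i, ord[seq_len(k - 1)]))
  }, integer(k)))
  if (k == 1) idx <- matrix(seq_len(n), ncol = 1)
  new_knn_graph(idx)
}

#' Fraction of differing edges between two kNN graphs
#'
#' `sum(|N_a - N_b|) / (2 sum(N_a))`: the fraction of all directed edges that
#' differ between the two graphs. 0 for identical graphs, 1 for edge-disjoint
#' ones; symmetric in its arguments since both graphs have `n * k` edges.
#'
#' @param g_a,g_b `knn_graph`s with the same `n` and `k`.
#' @return A number in `[0, 1]`.
#' @export
adjacency_error <- function(g_a, g_b) {
  if (g_a$n != g_b$n || g_a$k != g_b$k)
    stop("graphs must share n and k", call. = FALSE)
  A <- as_adjacency(g_a)
  B <- as_adjacency(g_b)
  sum(abs(A - B)) / (2 * sum(A))
}

# Symmetrized simple igraph (edge if either direction present, no self loops);
# shared by the graph metrics and Louvain clustering.
as_undirected_igraph <- function(graph) {
  A <- as_adjacency(graph)
  S <- ((A + Matrix::t(A)) > 0) * 1
  Matrix::diag(S) <- 0
  igraph::graph_from_adjacency_matrix(S, mode = "undirected")
}
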