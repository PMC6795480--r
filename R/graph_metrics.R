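#' Network-average clustering coefficient
#'
#' The directed kNN graph is symmetrized (edge if either direction is present)
#' and self-edges dropped. Each node's local clustering coefficient is the
#' fraction of its neighbor pairs that are themselves connected,
#' `a_i = 2 L_i / (k_i (k_i - 1))` with `L_i` the undirected edge count among
#' node i's neighbors; nodes of degree < 2 contribute 0. The NACC is the mean
#' over all nodes and quantifies how locally clique-like the graph is.
#'
#' @param graph A `knn_graph`.
#' @return A number in `[0, 1]`.
#' @export
nacc <- function(graph) {
  A <- as_adjacency(graph)
  S <- as.matrix((A + Matrix::t(A)) > 0) * 1
  diag(S) <- 0
  deg <- rowSums(S)
  a <- vapply(seq_len(nrow(S)), function(i) {
    if (deg[i] < 2) return(0)
    nb <- which(S[i, ] > 0)
    L <- sum(S[nb, nb]) / 2
    2 * L / (deg[i] * (deg[i] - 1))
  }, numeric(1))
  mean(a)
}

#' Modularity of a partition on the symmetrized kNN graph
#'
#' Newman modularity
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) [c_i == c_j]` on the
#' symmetrized simple graph, where `m` is the undirected edge count. Positive
#' Q means clusters hold more edges internally than a degree-preserving random
#' graph would place there; `Q <= 1`.
#'
#' @param graph A `knn_graph`.
#' @param partition Integer (or factor) cluster label per node.
#' @return Modularity Q.
#' @export
graph_modularity <- function(graph, partition) {
  A <- as_adjacency(graph)
  S <- as.matrix((A + Matrix::t(A)) > 0) * 1
  diag(S) <- 0
  if (nrow(S) == 0 || sum(S) == 0) stop("empty graph", call. = FALSE)
  lab <- as.integer(factor(partition))
  if (length(lab) != nrow(S))
    stop("partition must cover all nodes", call. = FALSE)
  deg <- rowSums(S)
  two_m <- sum(deg)
  same <- outer(lab, lab, "==")
  sum((S - outer(deg, deg) / two_m) * same) / two_m
}

#' Euclidean norm of the largest spatial dispersions
#'
#' Computes per-gene spatial dispersions on the given graph (neighborhood
#' averaging then Fano factor) and returns the Euclidean norm of the `top`
#' largest values — a scalar summary of how strongly gene expression is
#' spatially organized along the graph.
#'
#' @param graph A `knn_graph`.
#' @param E Log-scale cells x genes matrix.
#' @param top How many of the largest dispersions enter the norm
#'   (default 100).
#' @return Nonnegative number.
#' @export
dispersion_norm <- function(graph, E, top = 100) {
  f <- spatial_dispersion(knn_average(graph, E))$fano
  sqrt(sum(sort(f, decreasing = TRUE)[seq_len(min(top, length(f)))]^2))
}

#' Bundle the three graph-quality metrics
#'
#' NACC, modularity (for the supplied partition, or a Louvain partition if
#' none is given) and the spatial-dispersion norm for one graph + expression
#' matrix.
#'
#' @param graph A `knn_graph`.
#' @param E Log-scale cells x genes matrix.
#' @param partition Optional cluster labels; Louvain clustering is used when
#'   absent.
#' @param top Dispersion-norm pool size (default 100).
#' @param seed Seed for Louvain when `partition` is absent.
#' @return List of class `metrics_report`: `nacc`, `modularity`,
#'   `dispersion_norm`, `partition`.
#' @export
metrics_report <- function(graph, E, partition = NULL, top = 100, seed = 0L) {
  if (is.null(partition)) partition <- louvain_cluster(graph, seed = seed)
  structure(list(nacc = nacc(graph),
                 modularity = graph_modularity(graph, partition),
                 dispersion_norm = dispersion_norm(graph, E, top),
                 partition = partition),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("NACC %.4f | modularity %.4f | dispersion norm %.4f\n",
              x$nacc, x$modularity, x$dispersion_norm))
  invisible(x)
}
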