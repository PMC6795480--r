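#' Louvain clustering of a kNN graph
#'
#' Greedy modularity maximization on the symmetrized simple graph, seeded for
#' reproducibility.
#'
#' @param graph A `knn_graph`.
#' @param seed Integer seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @return Integer cluster label per cell (1-based, contiguous).
#' @export
louvain_cluster <- function(graph, seed = 0L, resolution = 1) {
  g <- as_undirected_igraph(graph)
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
  as.integer(factor(as.integer(memb)))
}

# Classic DBSCAN on a precomputed distance matrix. Core points have at least
# minPts points (self included) within eps; clusters are connected components
# of core points under eps-adjacency; border points join a core neighbor's
# cluster; the rest are outliers (label 0).
dbscan_distance <- function(D, eps, minPts) {
  n <- nrow(D)
  within <- D <= eps
  counts <- rowSums(within)
  core <- counts >= minPts
  labels <- integer(n)
  if (any(core)) {
    CC <- within[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(CC * 1, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[core] <- as.integer(comp)
    for (i in which(!core)) {
      nb <- which(within[i, ] & core)
      if (length(nb)) labels[i] <- labels[nb[which.min(D[i, nb])]]
    }
  }
  labels
}

#' Density-based clustering with kNN outlier rescue
#'
#' Density-based clustering of cells in the eigenvalue-weighted embedding;
#' cells the density clusterer deems outliers are then each assigned, in a
#' single pass, the majority cluster label among their `rescue_k` nearest
#' non-outlier cells (ties broken by the smallest label). Distances use the
#' same metric as the manifold reconstruction.
#'
#' @param embedding A `sam_pca` or numeric cells x components matrix.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param min_cluster_size Minimum cluster size / density threshold; default
#'   `max(5, n / 100)`.
#' @param rescue_k Neighbors consulted when rescuing an outlier (default 20).
#' @param eps Density radius; by default the 0.9 quantile of each cell's
#'   distance to its `min_cluster_size`-th nearest neighbor.
#' @return Integer labels (1-based, contiguous) with attribute `outlier`, the
#'   logical pre-rescue outlier mask.
#' @export
density_cluster_with_rescue <- function(embedding,
                                        metric = c("correlation", "euclidean"),
                                        min_cluster_size = NULL,
                                        rescue_k = 20, eps = NULL) {
  metric <- match.arg(metric)
  D <- cell_distances(embedding, metric)
  n <- nrow(D)
  if (is.null(min_cluster_size))
    min_cluster_size <- max(5, ceiling(n / 100))
  if (n < min_cluster_size)
    stop("fewer cells than min_cluster_size", call. = FALSE)
  if (is.null(eps)) {
    kdist <- apply(D, 1, function(d) sort(d)[min_cluster_size])
    eps <- as.numeric(quantile(kdist, 0.9))
  }
  labels <- dbscan_distance(D, eps, min_cluster_size)
  outlier <- labels == 0L
  if (all(outlier)) {
    warning("all cells flagged as outliers; returning a single cluster",
            call. = FALSE)
    labels <- rep(1L, n)
  } else if (any(outlier)) {
    clustered <- which(!outlier)
    for (i in which(outlier)) {
      ord <- clustered[order(D[i, clustered], clustered)]
      nb <- head(ord, min(rescue_k, length(ord)))
      tab <- table(labels[nb])
      best <- as.integer(names(tab)[tab == max(tab)])
      labels[i] <- min(best)
    }
  }
  out <- as.integer(factor(labels))
  attr(out, "outlier") <- outlier
  out
}

#' Contingency table between two cluster assignments
#'
#' @param x,y Cluster label vectors over the same cells.
#' @return List of class `contingency`: `n_ij` (overlap matrix), `a` (row
#'   sums), `b` (column sums), `n`.
#' @export
contingency <- function(x, y) {
  if (length(x) != length(y))
    stop("assignments cover different numbers of cells", call. = FALSE)
  tab <- table(x, y)
  structure(list(n_ij = unclass(tab), a = rowSums(tab), b = colSums(tab),
                 n = length(x)),
            class = "contingency")
}

choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table:
#' `ARI = (sum C(n_ij,2) - E) / (0.5 (sum C(a_i,2) + sum C(b_j,2)) - E)` with
#' `E = sum C(a_i,2) sum C(b_j,2) / C(n,2)`. 1 for identical partitions, ~0
#' for independent ones.
#'
#' @param x,y Cluster label vectors over the same cells.
#' @return A number in `(-1, 1]`.
#' @export
ari <- function(x, y) {
  ct <- contingency(x, y)
  sij <- sum(choose2(ct$n_ij))
  sa <- sum(choose2(ct$a))
  sb <- sum(choose2(ct$b))
  expd <- sa * sb / choose2(ct$n)
  den <- 0.5 * (sa + sb) - expd
  if (den == 0) return(1)  # both partitions trivial and identical in structure
  (sij - expd) / den
}

#' Per-cluster decomposition of the adjusted Rand index
#'
#' Leaves the ARI numerator unsummed over the reference clusters, giving one
#' score per cluster of `truth`; dividing the scores by the shared ARI
#' denominator and summing recovers the scalar ARI exactly. Because the
#' magnitude of a cluster's score depends on its size, a reference score —
#' the score the cluster would get if `truth` were compared against itself —
#' is reported alongside, and bounds the achieved score from above.
#'
#' @param x Cluster labels being evaluated.
#' @param truth Reference (ground-truth) cluster labels.
#' @return data.frame with one row per `truth` cluster: `cluster`, `score`
#'   (unsummed numerator term), `reference` (self-comparison score), and
#'   `normalized` (`score` / shared denominator); attribute `ari` holds the
#'   scalar index.
#' @export
per_cluster_ari <- function(x, truth) {
  ct <- contingency(x, truth)
  sa <- sum(choose2(ct$a))
  sb <- sum(choose2(ct$b))
  c2n <- choose2(ct$n)
  den <- 0.5 * (sa + sb) - sa * sb / c2n
  # numerator term for truth cluster j: sum_i C(n_ij,2) - sa * C(b_j,2) / C(n,2)
  score <- colSums(choose2(ct$n_ij)) - sa * choose2(ct$b) / c2n
  # reference: truth compared against itself, same decomposition
  ref <- choose2(ct$b) - sb * choose2(ct$b) / c2n
  data.frame(cluster = names(ct$b), score = as.numeric(score),
             reference = as.numeric(ref),
             normalized = as.numeric(score) / den,
             row.names = NULL, stringsAsFactors = FALSE) |>
    structure(ari = ari(x, truth))
}
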