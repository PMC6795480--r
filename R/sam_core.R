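#' Spatial dispersion (Fano factor of neighborhood-averaged expression)
#'
#' For each gene, the Fano factor `F = var(C_g) / mean(C_g)` of the
#' kNN-averaged expression column `C_g`, with the population (1/n) variance.
#' Genes whose expression varies across graph neighborhoods — rather than just
#' across individual cells — get high dispersion. Genes with zero mean get
#' dispersion 0 by convention.
#'
#' @param C Nonnegative cells x genes matrix of neighborhood-averaged
#'   expression (see [knn_average()]).
#' @return A data.frame with columns `gene`, `mean`, `var`, `fano`.
#' @export
spatial_dispersion <- function(C) {
  stopifnot_matrix(C, "C")
  if (any(C < 0))
    stop("dispersion requires a nonnegative matrix", call. = FALSE)
  mu <- colMeans(C)
  v <- col_pop_var(C)
  f <- ifelse(mu > 0, v / mu, 0)
  # guard tiny negative variances from floating point cancellation
  f[f < 0] <- 0
  data.frame(gene = gene_ids(C), mean = mu, var = pmax(v, 0), fano = f,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Saturated gene weights from spatial dispersions
#'
#' Dispersions are clamped at the saturation level `z` — the mean of the
#' largest `n_top` dispersions — and divided by `z`, yielding weights in
#' `[0, 1]`. Saturation stops a handful of extreme genes from flattening the
#' rest of the weight distribution. If every dispersion is 0, all weights
#' are 0.
#'
#' @param fano Nonnegative numeric vector of per-gene dispersions, or the
#'   data.frame returned by [spatial_dispersion()].
#' @param n_top Size of the saturation pool (default 50).
#' @return Named numeric weight vector with attribute `z`.
#' @export
compute_weights <- function(fano, n_top = 50) {
  if (is.data.frame(fano)) fano <- setNames(fano$fano, fano$gene)
  stopifnot(n_top >= 1, all(fano >= 0))
  m <- length(fano)
  z <- mean(sort(fano, decreasing = TRUE)[seq_len(min(n_top, m))])
  w <- if (z > 0) pmin(fano, z) / z else rep(0, m)
  if (is.null(names(w)) && !is.null(names(fano))) names(w) <- names(fano)
  attr(w, "z") <- z
  w
}

#' Rescale a normalized expression matrix by gene weights
#'
#' Multiplies column `i` of the standardized / L2-normalized matrix by weight
#' `W_i` (`E_hat = E_bar %*% diag(W)`), scaling each gene's variance by
#' `W_i^2` and attenuating genes that are uniform across neighborhoods.
#'
#' @param E_norm Normalized cells x genes matrix ([normalize_expression()]).
#' @param w Weight vector of length `ncol(E_norm)`; if both are named the
#'   names must agree.
#' @return The rescaled matrix.
#' @export
rescale_expression <- function(E_norm, w) {
  stopifnot_matrix(E_norm, "E_norm")
  if (length(w) != ncol(E_norm))
    stop("weight vector length does not match gene count", call. = FALSE)
  if (!is.null(names(w)) && !is.null(colnames(E_norm)) &&
      !identical(names(w), colnames(E_norm)))
    stop("gene ids of weights and matrix disagree", call. = FALSE)
  sweep(E_norm, 2, as.numeric(w), "*")
}

#' Eigenvalue-weighted PCA of the rescaled expression matrix
#'
#' Mean-centers the matrix, takes its SVD `E_mu = U S V'`, and returns the
#' principal components `P = U S`, eigenvalues `lambda = S^2 / (n - 1)`, gene
#' loadings `V`, and the eigenvalue-scaled components `P_hat = P diag(lambda)`.
#' All components up to `min(n - 1, m)` are kept by default: instead of
#' truncating to a subjective number of PCs, downstream distances weight each
#' component by its eigenvalue.
#'
#' @param E_hat Rescaled cells x genes matrix.
#' @param pc_cap Optional maximum number of components to retain.
#' @return An object of class `sam_pca`: list with `scores` (P), `d` (singular
#'   values), `lambda`, `loadings` (genes x components), `scaled` (P_hat) and
#'   `center` (the column means removed).
#' @export
weighted_pca <- function(E_hat, pc_cap = NULL) {
  stopifnot_matrix(E_hat, "E_hat")
  n <- nrow(E_hat)
  if (n < 2) stop("PCA needs at least 2 cells", call. = FALSE)
  ctr <- colMeans(E_hat)
  X <- sweep(E_hat, 2, ctr, "-")
  r <- min(n - 1, ncol(E_hat))
  if (!is.null(pc_cap)) r <- min(r, pc_cap)
  sv <- svd(X, nu = r, nv = r)
  d <- sv$d[seq_len(r)]
  P <- sweep(sv$u, 2, d, "*")
  lambda <- d^2 / (n - 1)
  rownames(P) <- rownames(E_hat)
  rownames(sv$v) <- colnames(E_hat)
  structure(list(scores = P, d = d, lambda = lambda, loadings = sv$v,
                 scaled = sweep(P, 2, lambda, "*"), center = ctr),
            class = "sam_pca")
}

#' @export
print.sam_pca <- function(x, ...) {
  cat("Eigenvalue-weighted PCA:", nrow(x$scores), "cells,",
      length(x$d), "components\n")
  invisible(x)
}

#' Pairwise cell distances in the weighted embedding
#'
#' Pearson correlation distance (`1 - r`, default) or Euclidean distance
#' between rows of the eigenvalue-scaled PC matrix. The diagonal is forced to
#' exactly 0. Under the correlation metric a zero-variance row is assigned the
#' maximum distance 2 to every other cell (0 to itself) so NaNs never
#' propagate.
#'
#' @param embedding A `sam_pca` object or a numeric cells x components matrix.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @return Symmetric n x n distance matrix.
#' @export
cell_distances <- function(embedding, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  X <- if (inherits(embedding, "sam_pca")) embedding$scaled else embedding
  stopifnot_matrix(X, "embedding")
  n <- nrow(X)
  if (metric == "correlation") {
    if (ncol(X) < 2)
      stop("correlation distance needs at least 2 components", call. = FALSE)
    rsd <- apply(X, 1, sd)
    D <- matrix(2, n, n)
    ok <- rsd > 0
    if (any(ok)) {
      R <- suppressWarnings(cor(t(X[ok, , drop = FALSE])))
      D[ok, ok] <- 1 - R
    }
  } else {
    D <- as.matrix(stats::dist(X))
  }
  diag(D) <- 0
  D[D < 0] <- 0
  unname(D)
}

#' Root-mean-square difference between two gene-weight vectors
#'
#' `sqrt(mean((w_a - w_b)^2))`; the convergence statistic compared against the
#' stopping threshold between adjacent iterations.
#'
#' @param w_a,w_b Weight vectors over the same genes.
#' @return Nonnegative number.
#' @export
weight_rmse <- function(w_a, w_b) {
  if (length(w_a) != length(w_b))
    stop("weight vectors differ in length", call. = FALSE)
  if (!is.null(names(w_a)) && !is.null(names(w_b)) &&
      !identical(names(w_a), names(w_b)))
    stop("weight vectors are over different genes", call. = FALSE)
  sqrt(mean((as.numeric(w_a) - as.numeric(w_b))^2))
}

#' Run the self-assembling manifold loop
#'
#' Starting from a random (or supplied) kNN graph, repeatedly: average
#' expression over neighborhoods, compute spatial dispersions and saturated
#' gene weights, rescale the normalized matrix, embed it with
#' eigenvalue-weighted PCA, recompute cell distances, and rebuild the kNN
#' graph. Stops when the RMSE between adjacent iterations' weight vectors
#' drops below `rmse_threshold`, or after `max_iter` iterations (with a
#' warning, `converged = FALSE`).
#'
#' @param E Filtered, noise-thresholded, log-scale cells x genes matrix.
#' @param k Neighborhood size including self (default 20).
#' @param n_top Saturation pool size for the weights (default 50).
#' @param norm_mode `"standardized"` (default) or `"l2"` normalization of `E`
#'   before weighting.
#' @param distance `"correlation"` (default) or `"euclidean"` cell distances.
#' @param max_iter Maximum iterations (default 10).
#' @param rmse_threshold Convergence threshold on the weight RMSE
#'   (default 5e-3).
#' @param seed Seed for the random initial graph.
#' @param pc_cap Optional cap on retained PCs (all kept by default).
#' @param dispersion_input Optional nonnegative matrix to compute dispersions
#'   from instead of `E` — used when `E` has been batch-corrected or had
#'   confounding components removed and may contain negative values, for which
#'   dispersion is ill-defined.
#' @param init_graph Optional starting `knn_graph` replacing the random
#'   initialization.
#'
#' @return An object of class `sam_fit`: list with `weights` (named vector
#'   with attribute `z`), `fano`, `graph` (final `knn_graph`), `pca`
#'   (`sam_pca`), `distances`, `trace` (per-iteration data.frame with
#'   `weight_rmse` and `adjacency_error`), `iterations`, `converged`, and the
#'   echoed parameters.
#' @export
run_sam <- function(E, k = 20, n_top = 50,
                    norm_mode = c("standardized", "l2"),
                    distance = c("correlation", "euclidean"),
                    max_iter = 10, rmse_threshold = 5e-3, seed = 0L,
                    pc_cap = NULL, dispersion_input = NULL,
                    init_graph = NULL) {
  norm_mode <- match.arg(norm_mode)
  distance <- match.arg(distance)
  stopifnot_matrix(E)
  check_finite(E)
  n <- nrow(E)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  stopifnot(n_top >= 1, rmse_threshold > 0, max_iter >= 1)

  D_in <- if (is.null(dispersion_input)) E else dispersion_input
  if (any(D_in < 0))
    stop("dispersion input must be nonnegative (log-scale expression)",
         call. = FALSE)
  if (!is.null(dispersion_input) && !all(dim(D_in) == dim(E)))
    stop("dispersion_input must match the shape of E", call. = FALSE)

  E_bar <- normalize_expression(E, norm_mode)
  graph <- if (is.null(init_graph)) random_knn_graph(n, k, seed) else init_graph
  if (graph$n != n || graph$k != k)
    stop("init_graph does not match n and k", call. = FALSE)

  w_prev <- NULL
  trace <- data.frame(iteration = integer(0), weight_rmse = numeric(0),
                      adjacency_error = numeric(0))
  converged <- FALSE
  w <- NULL; pca <- NULL; Dmat <- NULL; fano <- NULL

  for (it in seq_len(max_iter)) {
    C <- knn_average(graph, D_in)
    fano <- spatial_dispersion(C)
    w <- compute_weights(fano, n_top)
    E_hat <- rescale_expression(E_bar, w)
    pca <- weighted_pca(E_hat, pc_cap)
    Dmat <- cell_distances(pca, distance)
    new_graph <- update_knn(Dmat, k)
    adj_err <- adjacency_error(graph, new_graph)
    rmse <- if (is.null(w_prev)) NA_real_ else weight_rmse(w, w_prev)
    trace <- rbind(trace, data.frame(iteration = it, weight_rmse = rmse,
                                     adjacency_error = adj_err))
    graph <- new_graph
    w_prev <- w
    if (!is.na(rmse) && rmse < rmse_threshold) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("SAM did not converge within ", max_iter, " iterations",
            call. = FALSE)

  structure(list(weights = w, fano = fano, graph = graph, pca = pca,
                 distances = Dmat, trace = trace, iterations = nrow(trace),
                 converged = converged,
                 params = list(k = k, n_top = n_top, norm_mode = norm_mode,
                               distance = distance, max_iter = max_iter,
                               rmse_threshold = rmse_threshold, seed = seed,
                               pc_cap = pc_cap,
                               used_dispersion_input =
                                 !is.null(dispersion_input))),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM fit:", x$graph$n, "cells,", length(x$weights), "genes\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  last <- x$trace$weight_rmse[x$iterations]
  if (!is.na(last)) cat("  final weight RMSE:", format(last, digits = 4), "\n")
  cat("  saturation level z:", format(attr(x$weights, "z"), digits = 4), "\n")
  invisible(x)
}

#' Gene weight table of a SAM fit
#'
#' @param fit A `sam_fit`.
#' @return data.frame with `gene`, `fano`, `weight`, sorted by descending
#'   weight (ties by gene id).
#' @export
weight_table <- function(fit) {
  stopifnot(inherits(fit, "sam_fit"))
  df <- data.frame(gene = names(fit$weights), fano = fit$fano$fano,
                   weight = as.numeric(fit$weights),
                   stringsAsFactors = FALSE)
  df[order(-df$weight, df$gene), , drop = FALSE]
}
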