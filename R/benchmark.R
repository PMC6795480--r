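# Row-wise Pearson correlation of two equally shaped matrices; rows with zero
# variance in either matrix return NA.
rowwise_cor <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  r <- rowSums(A * B) / (na * nb)
  r[na == 0 | nb == 0] <- NA_real_
  r
}

#' Disagreement between two cell-cell distance matrices
#'
#' The mean, over cells, of the Pearson correlation distance between
#' corresponding rows of the two matrices. Rows are compared in full
#' (including the zero self-distance entry) unless `exclude_diag = TRUE`. A
#' cell whose distance row is constant in either matrix contributes the
#' zero-variance convention value 2.
#'
#' @param d_a,d_b n x n distance matrices.
#' @param exclude_diag Drop the self-distance entry from each row first.
#' @return Mean per-cell correlation distance, in `[0, 2]`.
#' @export
distance_matrix_error <- function(d_a, d_b, exclude_diag = FALSE) {
  if (!all(dim(d_a) == dim(d_b)))
    stop("distance matrices differ in shape", call. = FALSE)
  n <- nrow(d_a)
  if (exclude_diag) {
    keep <- !diag(TRUE, n)
    d_a <- matrix(t(d_a)[t(keep)], nrow = n, byrow = TRUE)
    d_b <- matrix(t(d_b)[t(keep)], nrow = n, byrow = TRUE)
  }
  r <- rowwise_cor(d_a, d_b)
  val <- 1 - r
  val[is.na(r)] <- 2
  mean(val)
}

#' Network sensitivity of a dataset
#'
#' How much the cell-cell distance structure depends on which genes are
#' measured: repeatedly subsample genes, run plain mean-centered PCA on the
#' subsample, build a correlation distance matrix from the top PCs, and
#' average the pairwise disagreement ([distance_matrix_error()]) over all
#' unordered replicate pairs. Redundant, structured data gives low
#' sensitivity; unstructured noise gives high sensitivity.
#'
#' @param E Log-scale cells x genes matrix.
#' @param n_genes Genes sampled per replicate, capped at `ncol(E)`
#'   (default 2000).
#' @param n_pcs PCs kept for the distance matrix (default 15).
#' @param n_reps Number of replicates (default 20).
#' @param seed Integer seed.
#' @param exclude_diag Passed to [distance_matrix_error()].
#' @return List of class `sensitivity_estimate`: `sensitivity`, `pairwise`
#'   (vector of S_jk), `params`.
#' @export
network_sensitivity <- function(E, n_genes = 2000, n_pcs = 15, n_reps = 20,
                                seed = 0L, exclude_diag = FALSE) {
  stopifnot_matrix(E)
  m <- ncol(E)
  if (m < 2) stop("need at least 2 genes", call. = FALSE)
  stopifnot(n_reps >= 2)
  n_genes <- min(n_genes, m)
  if (n_genes >= m && n_reps > 1)
    warning("gene subsample covers all genes; replicates are identical",
            call. = FALSE)
  n <- nrow(E)
  dmats <- with_seed(seed, lapply(seq_len(n_reps), function(r) {
    gi <- sample.int(m, n_genes)
    X <- E[, gi, drop = FALSE]
    X <- sweep(X, 2, colMeans(X), "-")
    p <- min(n_pcs, n - 1, n_genes)
    sv <- svd(X, nu = p, nv = 0)
    P <- sweep(sv$u, 2, sv$d[seq_len(p)], "*")
    cell_distances(P, "correlation")
  }))
  if (stats::var(as.numeric(E)) == 0)
    warning("constant expression matrix; sensitivity is degenerate",
            call. = FALSE)
  pairs <- utils::combn(n_reps, 2)
  s <- apply(pairs, 2, function(p)
    distance_matrix_error(dmats[[p[1]]], dmats[[p[2]]],
                          exclude_diag = exclude_diag))
  structure(list(sensitivity = mean(s), pairwise = s,
                 params = list(n_genes = n_genes, n_pcs = n_pcs,
                               n_reps = n_reps, seed = seed)),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("Network sensitivity: %.4f (%d replicate pairs)\n",
              x$sensitivity, length(x$pairwise)))
  invisible(x)
}

#' Corrupt an expression matrix by permuting a fraction of its entries
#'
#' Selects `floor(f * n * m)` matrix positions uniformly without replacement
#' and randomly permutes the values among those positions. All other entries
#' are untouched and the global multiset of values is preserved exactly, so
#' corruption destroys structure without changing the value distribution.
#'
#' @param E Cells x genes matrix.
#' @param f Corruption fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return Corrupted matrix of the same shape.
#' @export
corrupt <- function(E, f, seed = 0L) {
  stopifnot_matrix(E)
  stopifnot(f >= 0, f <= 1)
  npos <- floor(f * length(E))
  if (npos < 2) return(E)
  with_seed(seed, {
    pos <- sample.int(length(E), npos)
    E[pos] <- E[pos][sample.int(npos)]
  })
  E
}

#' Robustness of the pipeline under increasing corruption
#'
#' For each corruption fraction and replicate: corrupt the matrix, run the
#' full manifold reconstruction, cluster the embedding with
#' [density_cluster_with_rescue()], and record the ARI against the ground
#' truth plus the NACC, modularity and dispersion-norm of the final graph.
#'
#' @param E Preprocessed log-scale cells x genes matrix.
#' @param truth Ground-truth cluster labels.
#' @param fractions Increasing corruption fractions in `[0, 1]`.
#' @param n_reps Replicates per fraction (default 10).
#' @param seed Base seed; replicate r at fraction index i uses
#'   `seed + 1000 * i + r`.
#' @param ... Parameters passed to [run_sam()].
#' @return Object of class `corruption_curve`: `results` (long data.frame:
#'   `f`, `rep`, `metric`, `value`, `converged`) and `summary` (mean and sd
#'   per metric per f).
#' @export
corruption_curve <- function(E, truth, fractions = seq(0, 0.9, by = 0.1),
                             n_reps = 10, seed = 0L, ...) {
  stopifnot(length(truth) == nrow(E), !is.unsorted(fractions, strictly = TRUE))
  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    for (r in seq_len(n_reps)) {
      s <- seed + 1000L * i + r
      Ec <- corrupt(E, f, seed = s)
      fit <- suppressWarnings(run_sam(Ec, seed = s, ...))
      lab <- suppressWarnings(
        density_cluster_with_rescue(fit$pca, fit$params$distance))
      part <- louvain_cluster(fit$graph, seed = s)
      vals <- c(ari = ari(lab, truth),
                nacc = nacc(fit$graph),
                modularity = graph_modularity(fit$graph, part),
                dispersion_norm = dispersion_norm(fit$graph, Ec))
      rows[[length(rows) + 1]] <-
        data.frame(f = f, rep = r, metric = names(vals), value = unname(vals),
                   converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  agg_m <- stats::aggregate(value ~ f + metric, res, mean)
  agg_s <- stats::aggregate(value ~ f + metric, res, sd)
  names(agg_m)[3] <- "mean"
  agg_m$sd <- agg_s$value
  structure(list(results = res, summary = agg_m[order(agg_m$metric, agg_m$f), ],
                 fractions = fractions),
            class = "corruption_curve")
}

#' Range-normalized trapezoidal area under a metric-vs-corruption curve
#'
#' Integrates the per-fraction metric means over `f` with the trapezoidal
#' rule and divides by the `f` range, so a constant curve of value c has AUC
#' c and curves on different grids are comparable. Multiply by the range to
#' recover the raw integral.
#'
#' @param curve A `corruption_curve`, or a numeric vector of metric values.
#' @param metric Which metric to integrate when `curve` is a
#'   `corruption_curve`.
#' @param f Grid of fractions when `curve` is a plain vector.
#' @return Normalized AUC.
#' @export
auc_trapezoid <- function(curve, metric = "ari", f = NULL) {
  if (inherits(curve, "corruption_curve")) {
    s <- curve$summary[curve$summary$metric == metric, ]
    f <- s$f
    y <- s$mean
  } else {
    y <- as.numeric(curve)
  }
  if (length(y) < 2) stop("need at least 2 curve points", call. = FALSE)
  if (is.null(f) || length(f) != length(y))
    stop("`f` grid must match the curve values", call. = FALSE)
  pracma::trapz(f, y) / (max(f) - min(f))
}

#' Stability of the converged weights across random initializations
#'
#' Runs the manifold reconstruction `n_reps` times with distinct seeds and
#' returns the mean pairwise RMSE between the final gene-weight vectors.
#' Structured data converges to nearly identical weights from any
#' initialization; structure-free data does not.
#'
#' @param E Preprocessed log-scale cells x genes matrix.
#' @param n_reps Number of replicate runs (default 10).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param init_graphs Optional list of `knn_graph`s to start each replicate
#'   from (overrides the seeded random initialization).
#' @param ... Parameters passed to [run_sam()].
#' @return List of class `replicate_convergence`: `mean_rmse`, `pairwise`,
#'   `fits`.
#' @export
replicate_convergence <- function(E, n_reps = 10, seed = 0L,
                                  init_graphs = NULL, ...) {
  stopifnot(n_reps >= 2)
  fits <- lapply(seq_len(n_reps), function(r)
    suppressWarnings(run_sam(E, seed = seed + r,
                             init_graph = if (is.null(init_graphs)) NULL
                                          else init_graphs[[r]], ...)))
  pairs <- utils::combn(n_reps, 2)
  rm_pair <- apply(pairs, 2, function(p)
    weight_rmse(fits[[p[1]]]$weights, fits[[p[2]]]$weights))
  structure(list(mean_rmse = mean(rm_pair), pairwise = rm_pair, fits = fits),
            class = "replicate_convergence")
}
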