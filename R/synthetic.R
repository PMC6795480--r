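#' Structure-free Poisson-gamma expression matrix
#'
#' Null single-cell data with no intrinsic structure: each gene g draws a rate
#' `lambda_g ~ Gamma(shape, scale)` and every cell's count for g is an i.i.d.
#' `Poisson(lambda_g)` draw. Returned on the `log2(count + 1)` scale the
#' pipeline consumes. The gamma defaults (shape 2, scale 1) give realistic
#' sparsity after noise thresholding.
#'
#' @param n Cells.
#' @param m Genes.
#' @param gamma_shape,gamma_scale Gamma parameters for the per-gene rates.
#' @param seed Integer seed; regeneration is bit-identical.
#' @return Log-scale n x m matrix with cell/gene ids and attribute `lambda`
#'   (the per-gene rates).
#' @export
random_poisson_gamma <- function(n, m, gamma_shape = 2, gamma_scale = 1,
                                 seed = 0L) {
  stopifnot(n >= 1, m >= 1, gamma_shape > 0, gamma_scale > 0)
  with_seed(seed, {
    lambda <- rgamma(m, shape = gamma_shape, scale = gamma_scale)
    counts <- matrix(rpois(n * m, rep(lambda, each = n)), nrow = n)
    E <- log2(counts + 1)
    dimnames(E) <- list(paste0("cell", seq_len(n)), paste0("gene", seq_len(m)))
    attr(E, "lambda") <- setNames(lambda, colnames(E))
    E
  })
}

#' Structured synthetic dataset with planted clusters and markers
#'
#' Poisson-gamma background with cells split near-evenly into `n_clusters`
#' groups; each group owns `markers_per_cluster` disjoint marker genes whose
#' Poisson rate is multiplied by `effect` in that group only. The planted
#' labels and marker lists are returned as ground truth for benchmarking.
#'
#' @param n Cells.
#' @param m Genes (`n_clusters * markers_per_cluster <= m`).
#' @param n_clusters Number of planted groups (default 3).
#' @param markers_per_cluster Marker genes per group (default 10).
#' @param effect Fold change (> 1) applied to a marker's rate inside its
#'   group (default 4).
#' @param gamma_shape,gamma_scale Background rate distribution.
#' @param seed Integer seed.
#' @return Object of class `synthetic_dataset`: `E` (log-scale matrix),
#'   `labels` (integer per cell), `markers` (list of gene-id vectors per
#'   cluster), `params`.
#' @export
structured_clusters <- function(n, m, n_clusters = 3, markers_per_cluster = 10,
                                effect = 4, gamma_shape = 2, gamma_scale = 1,
                                seed = 0L) {
  stopifnot(n_clusters >= 1, effect >= 1,
            n_clusters * markers_per_cluster <= m)
  with_seed(seed, {
    lambda <- rgamma(m, shape = gamma_shape, scale = gamma_scale)
    labels <- sort(rep_len(seq_len(n_clusters), n))
    marker_idx <- matrix(sample.int(m, n_clusters * markers_per_cluster),
                         nrow = n_clusters)
    lam_mat <- matrix(rep(lambda, each = n), nrow = n)
    for (cl in seq_len(n_clusters)) {
      rows <- labels == cl
      lam_mat[rows, marker_idx[cl, ]] <-
        lam_mat[rows, marker_idx[cl, ], drop = FALSE] * effect
    }
    counts <- matrix(rpois(n * m, lam_mat), nrow = n)
    E <- log2(counts + 1)
    dimnames(E) <- list(paste0("cell", seq_len(n)), paste0("gene", seq_len(m)))
    markers <- lapply(seq_len(n_clusters),
                      function(cl) colnames(E)[sort(marker_idx[cl, ])])
    structure(list(E = E, labels = labels, markers = markers,
                   confound_genes = NULL, confound_score = NULL,
                   params = list(n = n, m = m, n_clusters = n_clusters,
                                 markers_per_cluster = markers_per_cluster,
                                 effect = effect, gamma_shape = gamma_shape,
                                 gamma_scale = gamma_scale, seed = seed)),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$E), "cells x", ncol(x$E), "genes,",
      length(unique(x$labels)), "planted cluster(s)\n")
  if (!is.null(x$confound_genes))
    cat("  confound signature on", length(x$confound_genes), "genes\n")
  invisible(x)
}

#' Append high-variance, cluster-uniform noise genes
#'
#' Adds genes that are highly variable across individual cells but identically
#' distributed in every planted cluster: highly expressed, bursty genes whose
#' per-cell Poisson rate is drawn i.i.d. from a gamma with mean
#' `mean_boost`-fold the background mean and count-scale Fano factor
#' `1 + dispersion_boost`. Such genes dominate per-cell variance rankings —
#' the classic highly-variable-gene trap — yet carry no topological signal,
#' and the log transform compresses their relative variation, so their
#' spatial dispersion along any graph is low.
#'
#' @param ds A `synthetic_dataset`.
#' @param n_noise Number of genes to append.
#' @param dispersion_boost Overdispersion of the per-cell rate: the appended
#'   genes' count-scale Fano factor is `1 + dispersion_boost` (default 3,
#'   versus 1 for the Poisson background).
#' @param mean_boost Mean expression relative to the background mean
#'   (default 10).
#' @param p_off Probability a cell is in a transcriptional off state for the
#'   gene (count 0), keeping the genes within the prevalence filter's band
#'   and adding burst-like variance (default 0.03).
#' @param seed Integer seed.
#' @return The dataset with `noise` gene ids recorded in `$noise_genes`.
#' @export
add_noise_genes <- function(ds, n_noise, dispersion_boost = 3,
                            mean_boost = 10, p_off = 0.03, seed = 0L) {
  stopifnot(inherits(ds, "synthetic_dataset"), n_noise >= 1,
            dispersion_boost > 0, mean_boost > 0, p_off >= 0, p_off < 1)
  p <- ds$params
  n <- nrow(ds$E)
  with_seed(seed, {
    # per-cell rates: Gamma with mean mu and Var(lambda) = dispersion_boost
    # * mu, so counts have Fano 1 + dispersion_boost in the on state
    mu <- mean_boost * p$gamma_shape * p$gamma_scale
    lam <- matrix(rgamma(n * n_noise, shape = mu / dispersion_boost,
                         scale = dispersion_boost), nrow = n)
    lam[matrix(runif(n * n_noise) < p_off, nrow = n)] <- 0
    counts <- matrix(rpois(n * n_noise, lam), nrow = n)
    noise <- log2(counts + 1)
    colnames(noise) <- paste0("noise", seq_len(n_noise))
    rownames(noise) <- rownames(ds$E)
    ds$E <- cbind(ds$E, noise)
    ds$noise_genes <- colnames(noise)
    ds$params$n_noise <- n_noise
    ds$params$dispersion_boost <- dispersion_boost
    ds
  })
}

#' Plant a label-independent confounding signature
#'
#' Draws a latent per-cell score (uniform on [0, 1], independent of the
#' planted labels) and adds `amplitude * score` to the log expression of
#' `n_confound_genes` randomly chosen non-marker genes — emulating a global
#' process such as the cell cycle that dominates variation and masks the
#' cluster structure. The affected gene ids form the gene set used for
#' confound removal.
#'
#' @param ds A `synthetic_dataset`.
#' @param n_confound_genes Genes carrying the signature.
#' @param amplitude Log2-scale amplitude of the signature.
#' @param seed Integer seed.
#' @return The dataset with `confound_genes` and per-cell `confound_score`
#'   recorded.
#' @export
add_confound_signature <- function(ds, n_confound_genes, amplitude,
                                   seed = 0L) {
  stopifnot(inherits(ds, "synthetic_dataset"),
            n_confound_genes <= ncol(ds$E), amplitude >= 0)
  with_seed(seed, {
    pool <- setdiff(colnames(ds$E), unlist(ds$markers))
    genes <- sample(pool, n_confound_genes)
    score <- runif(nrow(ds$E))
    if (amplitude > 0)
      ds$E[, genes] <- ds$E[, genes] + outer(score, rep(amplitude,
                                                        n_confound_genes))
    ds$confound_genes <- sort(genes)
    ds$confound_score <- score
    ds$params$amplitude <- amplitude
    ds
  })
}

#' Globally shuffle all entries of an expression matrix
#'
#' Randomly permutes all `n * m` entries — equivalent to [corrupt()] with
#' `f = 1` — producing a structure-free matrix with exactly the original
#' value multiset. The standard negative control: a manifold reconstruction
#' run on the shuffle should show no improvement in graph quality over its
#' random initialization.
#'
#' @param E Cells x genes matrix.
#' @param seed Integer seed.
#' @return Shuffled matrix of the same shape and dimnames.
#' @export
shuffle_matrix <- function(E, seed = 0L) {
  corrupt(E, 1, seed = seed)
}

#' The canonical structured benchmarking fixture
#'
#' 300 cells x 2000 genes, 3 planted clusters with 10 four-fold markers each
#' on a Poisson-gamma background (shape 2, scale 1), generated at a fixed
#' seed and preprocessed with the standard noise threshold + prevalence
#' filter. Used throughout the package's tests and benchmarks.
#'
#' @param seed Generator seed (default 0).
#' @param preprocess Apply [preprocess_expression()] to `$E` (default TRUE).
#' @return A `synthetic_dataset`.
#' @export
canonical_fixture <- function(seed = 0L, preprocess = TRUE) {
  ds <- structured_clusters(n = 300, m = 2000, n_clusters = 3,
                            markers_per_cluster = 10, effect = 4,
                            gamma_shape = 2, gamma_scale = 1, seed = seed)
  if (preprocess) ds$E <- preprocess_expression(ds$E)
  ds
}

#' The canonical confounded fixture
#'
#' Structured dataset (300 cells x 2000 genes, 3 clusters) with a richer
#' marker signature (30 four-fold markers per cluster, emulating the
#' redundant expression programs of real cell types) plus a dominant
#' label-independent confounding signature (60 genes, log2 amplitude 3).
#' Plain manifold reconstruction organizes cells along the confound; the
#' gene-set PC-removal workflow recovers the planted clusters.
#'
#' @param seed Generator seed (default 0); the confound uses `seed + 1`.
#' @param preprocess Apply [preprocess_expression()] to `$E` (default TRUE).
#' @return A `synthetic_dataset` with `confound_genes` recorded.
#' @export
confounded_fixture <- function(seed = 0L, preprocess = TRUE) {
  ds <- structured_clusters(n = 300, m = 2000, n_clusters = 3,
                            markers_per_cluster = 30, effect = 4,
                            gamma_shape = 2, gamma_scale = 1, seed = seed)
  ds <- add_confound_signature(ds, n_confound_genes = 60, amplitude = 3,
                               seed = seed + 1L)
  if (preprocess) ds$E <- preprocess_expression(ds$E)
  ds
}
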