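test_that("spatial dispersion is the population Fano factor with 0/0 = 0", {
  C <- cbind(a = c(0, 0, 4, 4), b = rep(2, 4), c = rep(0, 4))
  f <- spatial_dispersion(C)
  expect_equal(f$fano, c(2, 0, 0))   # var 4 / mean 2; constant; all-zero
  expect_equal(f$mean, c(2, 2, 0))
  expect_error(spatial_dispersion(cbind(c(-1, 1))), "nonnegative")
})

test_that("weights saturate at the mean of the top dispersions", {
  w <- compute_weights(c(10, 5, 1, 0), n_top = 2)
  expect_equal(as.numeric(w), c(1, 2 / 3, 2 / 15, 0))
  expect_equal(attr(w, "z"), 7.5)
  expect_equal(as.numeric(compute_weights(rep(3, 5), n_top = 2)), rep(1, 5))
  expect_equal(as.numeric(compute_weights(rep(0, 4))), rep(0, 4))
  # n_top larger than the gene count falls back to all genes
  expect_equal(attr(compute_weights(c(2, 4), n_top = 10), "z"), 3)
})

test_that("rescaling multiplies gene columns by weights", {
  E <- tiny_matrix(8, 3)
  En <- normalize_expression(E, "standardized")
  expect_equal(rescale_expression(En, c(1, 1, 1)), En)
  out <- rescale_expression(En, c(0, 0.5, 1))
  expect_true(all(out[, 1] == 0))
  v <- function(x) mean(x^2) - mean(x)^2
  expect_equal(v(out[, 2]), 0.25 * v(En[, 2]))
})

test_that("weighted PCA satisfies the SVD identities", {
  # hand-checked 2x2 case: single informative component
  X <- rbind(c(1, 0), c(-1, 0))
  p <- weighted_pca(X)
  expect_equal(abs(p$scores[, 1]), c(1, 1), ignore_attr = TRUE)
  expect_equal(p$lambda[1], 2)
  expect_equal(abs(p$scaled[, 1]), c(2, 2), ignore_attr = TRUE)
  # identical rows: centering kills everything
  p0 <- weighted_pca(matrix(1, 4, 3))
  expect_true(all(abs(p0$scaled) < 1e-12))
  # reconstruction on a random matrix
  set.seed(5)
  Y <- matrix(rnorm(20 * 50), 20, 50)
  py <- weighted_pca(Y)
  Yc <- sweep(Y, 2, py$center, "-")
  expect_lt(max(abs(py$scores %*% t(py$loadings) - Yc)), 1e-8)
  # eigenvalues nonincreasing, orthogonal scores
  expect_true(all(diff(py$lambda) <= 1e-12))
  G <- crossprod(py$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # sum of eigenvalues = total population column variance * n/(n-1)
  vtot <- sum(colMeans(Yc^2))
  expect_equal(sum(py$lambda), vtot * nrow(Y) / (nrow(Y) - 1))
  expect_error(weighted_pca(Y[1, , drop = FALSE]), "at least 2")
})

test_that("cell distances match hand-computed correlation and euclidean values", {
  X <- rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3))
  D <- cell_distances(X, "correlation")
  expect_equal(D[1, 2], 2)        # perfectly anticorrelated
  expect_equal(D[1, 3], 0)        # identical
  expect_equal(diag(D), rep(0, 3))
  expect_equal(D, t(D))
  De <- cell_distances(rbind(c(0, 0), c(3, 4)), "euclidean")
  expect_equal(De[1, 2], 5)
  # zero-variance row gets max distance 2 off-diagonal
  Dz <- cell_distances(rbind(c(1, 1, 1), c(1, 2, 3), c(3, 2, 1)),
                       "correlation")
  expect_equal(Dz[1, 2], 2)
  expect_equal(Dz[1, 1], 0)
  expect_false(anyNA(Dz))
})

test_that("weight RMSE matches its closed form", {
  expect_equal(weight_rmse(c(1, 0), c(1, 0)), 0)
  expect_equal(weight_rmse(c(1, 0), c(0, 1)), 1)
  expect_equal(weight_rmse(c(0.5, 0.5), c(0.5, 0.6)), sqrt(0.005))
  expect_error(weight_rmse(c(1, 0), c(1, 0, 0)), "length")
})

test_that("the SAM loop is deterministic and converges on structured data", {
  ds <- canonical_fixture(0)
  fit <- run_sam(ds$E, seed = 1, max_iter = 20)
  expect_true(fit$converged)
  expect_lt(fit$trace$weight_rmse[fit$iterations], 5e-3)
  # weights bounded in [0,1], max weight 1
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_equal(max(fit$weights), 1)
  # bit-identical reproduction under the same seed
  fit2 <- run_sam(ds$E, seed = 1, max_iter = 20)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$weights, fit2$weights)
  # planted markers dominate the weight ranking
  wt <- weight_table(fit)
  expect_true(all(match(unlist(ds$markers), wt$gene) <= 30))
  # final graph beats the random initial graph on both structure metrics
  g0 <- random_knn_graph(nrow(ds$E), 20, seed = 1)
  expect_gt(nacc(fit$graph), nacc(g0))
  expect_gt(graph_modularity(fit$graph, louvain_cluster(fit$graph, 1)),
            graph_modularity(g0, louvain_cluster(g0, 1)))
})

test_that("constant genes keep zero weight through every iteration", {
  ds <- canonical_fixture(0)
  E <- cbind(ds$E[, 1:200], const = 2)
  fit <- suppressWarnings(run_sam(E, seed = 1, max_iter = 3))
  expect_equal(as.numeric(fit$weights["const"]), 0)
})

test_that("run_sam validates input and honours a user-supplied initial graph", {
  E <- tiny_matrix(30, 10)
  Ebad <- E; Ebad[1, 1] <- NA
  expect_error(run_sam(Ebad, k = 3), "non-finite")
  expect_error(run_sam(E, k = 30), "smaller")
  g0 <- random_knn_graph(30, 3, seed = 9)
  f1 <- suppressWarnings(run_sam(E, k = 3, max_iter = 2, init_graph = g0))
  f2 <- suppressWarnings(run_sam(E, k = 3, max_iter = 2, init_graph = g0,
                                 seed = 123))
  expect_identical(f1$trace, f2$trace)  # init graph overrides the seed
  # non-convergence warns but returns a result
  expect_warning(run_sam(E, k = 3, max_iter = 1), "did not converge")
})
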