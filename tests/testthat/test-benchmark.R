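test_that("distance-matrix error is the mean per-row correlation distance", {
  set.seed(71)
  D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  expect_equal(distance_matrix_error(D, D), 0)
  # scale invariance of correlation
  expect_equal(distance_matrix_error(D, 2 * D), 0)
  # anti-ordered rows: distance 2 per row
  A <- matrix(rep(1:5, 4), 4, 5, byrow = TRUE)
  B <- matrix(rep(5:1, 4), 4, 5, byrow = TRUE)
  expect_equal(distance_matrix_error(A, B), 2)
  # a constant row contributes the zero-variance convention value 2
  A2 <- A; A2[1, ] <- 3
  expect_equal(distance_matrix_error(A2, A),
               (2 + 0 + 0 + 0) / 4)
  expect_error(distance_matrix_error(D, D[1:5, 1:5]), "shape")
})

test_that("network sensitivity separates redundant from noisy data", {
  set.seed(72)
  # genes all copies of one profile: subsamples identical, sensitivity ~ 0
  profile <- rnorm(60)
  Ered <- matrix(rep(profile, 40), 60, 40) + 5
  Ered <- abs(Ered)
  s_red <- suppressWarnings(network_sensitivity(Ered, n_genes = 10,
                                                n_pcs = 5, n_reps = 6,
                                                seed = 1))
  En <- preprocess_expression(random_poisson_gamma(60, 400, seed = 2))
  s_noise <- network_sensitivity(En, n_genes = 100, n_pcs = 5, n_reps = 6,
                                 seed = 1)
  expect_lt(s_red$sensitivity, 0.05)
  expect_gt(s_noise$sensitivity, s_red$sensitivity * 10)
  expect_length(s_red$pairwise, choose(6, 2))
  # seeded reproducibility
  expect_equal(network_sensitivity(En, n_genes = 100, n_pcs = 5, n_reps = 6,
                                   seed = 1)$sensitivity,
               s_noise$sensitivity)
})

test_that("sensitivity is gene-order invariant at the distribution level", {
  E <- preprocess_expression(random_poisson_gamma(50, 300, seed = 3))
  set.seed(4)
  Eperm <- E[, sample(ncol(E))]
  s1 <- vapply(1:20, function(s)
    network_sensitivity(E, n_genes = 80, n_pcs = 5, n_reps = 4,
                        seed = s)$sensitivity, numeric(1))
  s2 <- vapply(1:20, function(s)
    network_sensitivity(Eperm, n_genes = 80, n_pcs = 5, n_reps = 4,
                        seed = 100 + s)$sensitivity, numeric(1))
  se <- sqrt(var(s1) / 20 + var(s2) / 20)
  expect_lt(abs(mean(s1) - mean(s2)), 2 * se + 1e-8)
})

test_that("corruption permutes exactly the selected entries and conserves values", {
  E <- tiny_matrix(10, 10)
  expect_identical(corrupt(E, 0, seed = 1), E)
  for (f in c(0.25, 0.5, 1)) {
    Ec <- corrupt(E, f, seed = 5)
    expect_equal(sort(as.numeric(Ec)), sort(as.numeric(E)))
    expect_lte(sum(Ec != E), floor(f * 100))
  }
  # exactly floor(f n m) positions are drawn (entries with duplicate values
  # may land unchanged, so count via a matrix of unique values)
  U <- matrix(seq_len(100), 10, 10) + 0.5
  expect_lte(sum(corrupt(U, 0.5, seed = 6) != U), 50)
  expect_gt(sum(corrupt(U, 0.5, seed = 6) != U), 40)
  # shuffle is corruption at f = 1
  expect_identical(shuffle_matrix(E, seed = 9), corrupt(E, 1, seed = 9))
})

test_that("trapezoidal AUC matches closed forms and is range-normalized", {
  expect_equal(auc_trapezoid(rep(0.7, 5), f = seq(0, 1, length.out = 5)), 0.7)
  expect_equal(auc_trapezoid(c(1, 0), f = c(0, 1)), 0.5)
  # collinear midpoint changes nothing
  expect_equal(auc_trapezoid(c(1, 0.5, 0), f = c(0, 0.5, 1)), 0.5)
  # piecewise-linear closed form
  expect_equal(auc_trapezoid(c(0, 1, 1, 0), f = c(0, 0.25, 0.75, 1)),
               (0.125 + 0.5 + 0.125) / 1)
  expect_error(auc_trapezoid(1, f = 0.5), "at least 2")
})

test_that("a small corruption curve reproduces the uncorrupted run at f = 0", {
  ds <- canonical_fixture(0)
  E <- ds$E[, 1:600]
  curve <- corruption_curve(E, ds$labels, fractions = c(0, 1), n_reps = 1,
                            seed = 3, max_iter = 5, k = 10)
  s <- curve$summary
  ari0 <- s$mean[s$metric == "ari" & s$f == 0]
  # f = 0 replicate equals a direct uncorrupted run with the same seed
  fit <- suppressWarnings(run_sam(E, seed = 1003 + 1, max_iter = 5, k = 10))
  lab <- suppressWarnings(density_cluster_with_rescue(fit$pca))
  expect_equal(ari0, ari(lab, ds$labels))
  # fully permuted data carries no label information
  expect_lt(s$mean[s$metric == "ari" & s$f == 1], 0.1)
  expect_s3_class(plot_corruption(curve), "ggplot")
})

test_that("replicate convergence separates structured from null data", {
  ds <- canonical_fixture(0)
  E <- ds$E[, 1:500]
  rc <- replicate_convergence(E, n_reps = 3, seed = 7, max_iter = 8, k = 10)
  expect_length(rc$pairwise, 3)
  # identical supplied initial graphs across replicates give RMSE 0
  g0 <- random_knn_graph(nrow(E), 10, seed = 1)
  rc0 <- replicate_convergence(E, n_reps = 3, seed = 7, max_iter = 3, k = 10,
                               init_graphs = list(g0, g0, g0))
  expect_equal(rc0$mean_rmse, 0)
})
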