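test_that("Poisson-gamma null data is reproducible with correct shape and means", {
  E <- random_poisson_gamma(50, 30, seed = 5)
  expect_equal(dim(E), c(50, 30))
  expect_identical(E, random_poisson_gamma(50, 30, seed = 5))
  expect_false(identical(E, random_poisson_gamma(50, 30, seed = 6)))
  # pre-log per-gene means track the sampled rates (CLT bound)
  big <- random_poisson_gamma(5000, 20, seed = 7)
  lam <- attr(big, "lambda")
  counts <- 2^big - 1
  dev <- abs(colMeans(counts) - lam)
  expect_true(all(dev <= 4 * sqrt(lam / 5000) + 1e-9))
})

test_that("structured clusters plant recoverable marker effects", {
  ds <- structured_clusters(300, 400, n_clusters = 3, markers_per_cluster = 5,
                            effect = 4, seed = 9)
  expect_equal(sort(unique(ds$labels)), 1:3)
  expect_length(unlist(ds$markers), 15)
  expect_false(any(duplicated(unlist(ds$markers))))
  # planted fold-change recovered from pre-log means: within 25% wherever the
  # baseline is informative (mean count >= 0.5), median error well below that
  counts <- 2^ds$E - 1
  stats <- do.call(rbind, lapply(1:3, function(cl) {
    t(vapply(ds$markers[[cl]], function(g) {
      base <- mean(counts[ds$labels != cl, g])
      c(base = base, ratio = mean(counts[ds$labels == cl, g]) / base)
    }, numeric(2)))
  }))
  relerr <- abs(stats[, "ratio"] - 4) / 4
  expect_true(all(relerr[stats[, "base"] >= 0.5] < 0.25))
  expect_lt(median(relerr), 0.15)
  # regeneration is bit-identical
  ds2 <- structured_clusters(300, 400, n_clusters = 3,
                             markers_per_cluster = 5, effect = 4, seed = 9)
  expect_identical(ds$E, ds2$E)
})

test_that("marker effects are detectable only at the planted loci", {
  ds <- structured_clusters(200, 1000, n_clusters = 2,
                            markers_per_cluster = 10, effect = 4, seed = 13)
  pvals <- vapply(colnames(ds$E), function(g)
    stats::wilcox.test(ds$E[ds$labels == 1, g],
                       ds$E[ds$labels == 2, g], exact = FALSE)$p.value,
    numeric(1))
  mk <- unlist(ds$markers)
  expect_true(all(pvals[mk] < 1e-4))
  # type-I control at non-marker genes, Bonferroni-ish check
  others <- setdiff(colnames(ds$E), mk)
  expect_lt(mean(pvals[others] < 0.01, na.rm = TRUE), 0.03)
})

test_that("effect = 1 reduces to the null generator", {
  ds <- structured_clusters(100, 200, effect = 1, seed = 17)
  En <- random_poisson_gamma(100, 200, seed = 17)
  ks <- suppressWarnings(stats::ks.test(as.numeric(ds$E), as.numeric(En)))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise genes are high-variance on the count scale yet label-free", {
  ds <- structured_clusters(150, 300, seed = 19)
  ds <- add_noise_genes(ds, 20, seed = 20)
  expect_length(ds$noise_genes, 20)
  expect_identical(ds$labels, structured_clusters(150, 300, seed = 19)$labels)
  counts <- 2^ds$E - 1
  fano <- apply(counts, 2, function(x) var(x) / max(mean(x), 1e-12))
  expect_true(all(fano[ds$noise_genes] > median(fano)))
  # no label association in the noise genes
  pv <- vapply(ds$noise_genes, function(g)
    stats::kruskal.test(ds$E[, g], ds$labels)$p.value, numeric(1))
  expect_gt(min(p.adjust(pv, "BH")), 0.05)
})

test_that("the confound signature is latent, label-independent and removable", {
  ds0 <- structured_clusters(100, 300, seed = 23)
  # amplitude zero changes nothing
  ds_a0 <- add_confound_signature(ds0, 30, 0, seed = 24)
  expect_identical(ds_a0$E, ds0$E)
  ds <- add_confound_signature(ds0, 30, 2, seed = 24)
  expect_length(ds$confound_genes, 30)
  expect_false(any(ds$confound_genes %in% unlist(ds$markers)))
  # affected genes correlate with the latent score, others do not
  cors <- vapply(colnames(ds$E), function(g)
    suppressWarnings(cor(ds$E[, g], ds$confound_score)), numeric(1))
  expect_gt(min(abs(cors[ds$confound_genes])), 0.3)
  expect_lt(stats::median(abs(cors[setdiff(colnames(ds$E),
                                           ds$confound_genes)]),
                          na.rm = TRUE), 0.2)
})

test_that("the confounded fixture selects at least one removable component", {
  ds <- confounded_fixture(0)
  fit <- suppressWarnings(run_sam(ds$E, seed = 3, max_iter = 20))
  m <- pc_gene_association(fit$pca,
                           intersect(ds$confound_genes, colnames(ds$E)))
  expect_gte(length(m$selected), 1)
})

test_that("global shuffling preserves the value multiset", {
  E <- tiny_matrix(8, 9)
  Es <- shuffle_matrix(E, seed = 27)
  expect_equal(sort(as.numeric(Es)), sort(as.numeric(E)))
  expect_false(identical(Es, E))
  expect_identical(Es, shuffle_matrix(E, seed = 27))
})
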