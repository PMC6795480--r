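# Independent brute-force oracles used to cross-check the implementation.

# ARI by pair counting over all C(n,2) cell pairs.
ari_pair_counting <- function(x, y) {
  n <- length(x)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]
    sy <- y[i] == y[j]
    if (sx && sy) n11 <- n11 + 1
    else if (!sx && !sy) n00 <- n00 + 1
    else if (sx) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  num / den
}

# Local clustering coefficients by exhaustive neighbor-pair enumeration on a
# symmetric 0/1 adjacency matrix without self loops.
nacc_brute <- function(S) {
  n <- nrow(S)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(S[i, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    cnt <- 0
    for (a in seq_len(d - 1)) for (b in (a + 1):d)
      if (S[nb[a], nb[b]] > 0) cnt <- cnt + 1
    cnt / (d * (d - 1) / 2)
  }, numeric(1)))
}

# Modularity by direct double sum over ordered node pairs.
modularity_brute <- function(S, lab) {
  deg <- rowSums(S)
  two_m <- sum(deg)
  q <- 0
  n <- nrow(S)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (lab[i] == lab[j]) q <- q + S[i, j] - deg[i] * deg[j] / two_m
  q / two_m
}

# Random symmetric simple graph on n nodes with edge probability p.
random_sym_graph <- function(n, p) {
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) S[i, j] <- S[j, i] <- 1
  S
}

# Symmetrized simple adjacency of a knn_graph, as a dense base matrix.
sym_adjacency <- function(graph) {
  A <- as.matrix(as_adjacency(graph))
  S <- ((A + t(A)) > 0) * 1
  diag(S) <- 0
  S
}

# knn_graph from an explicit neighbor index list (rows include self). Rows
# shorter than the longest are padded with repeats of the self index, which
# collapse to a single edge in the 0/1 adjacency.
graph_from_rows <- function(rows) {
  k <- max(lengths(rows))
  idx <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- as.integer(rows[[i]])
    sort(c(r, rep(i, k - length(r))))
  }))
  samgraph:::new_knn_graph(idx)
}

# Small deterministic expression fixture for plumbing tests.
tiny_matrix <- function(n = 6, m = 8, seed = 1) {
  set.seed(seed)
  E <- matrix(round(runif(n * m, 0, 5), 3), n, m,
              dimnames = list(paste0("c", seq_len(n)),
                              paste0("g", seq_len(m))))
  E
}
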