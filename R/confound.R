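#' Associate principal components with a gene set
#'
#' For each component j the association with the gene set G (e.g. cell-cycle
#' genes) is the mean absolute loading `A_j = (1/|G|) sum_{i in G} |L_ji|`.
#' Components whose association is at least two (population) standard
#' deviations above the mean association are selected for removal.
#'
#' @param embedding A `sam_pca` (its `loadings` are used) or a genes x
#'   components loading matrix with gene rownames.
#' @param gene_set Character vector of gene ids.
#' @param n_sd Selection threshold in SDs above the mean (default 2).
#' @return List of class `confound_model`: `association` (per component),
#'   `selected` (component indices), `threshold`, `gene_set` (resolved ids).
#' @export
pc_gene_association <- function(embedding, gene_set, n_sd = 2) {
  L <- if (inherits(embedding, "sam_pca")) embedding$loadings else embedding
  if (is.null(rownames(L)))
    stop("loadings must carry gene ids as rownames", call. = FALSE)
  idx <- match(gene_set, rownames(L))
  missing <- gene_set[is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    stop("no gene-set members found in the loadings; unmatched ids: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  A <- colMeans(abs(L[idx, , drop = FALSE]))
  mu <- mean(A)
  s <- sqrt(mean((A - mu)^2))  # population SD
  thr <- mu + n_sd * s
  # degenerate spread (e.g. gene set absent from every component): nothing
  # stands out, select nothing
  sel <- if (s > 0) which(A >= thr) else integer(0)
  structure(list(association = A, selected = sel, threshold = thr,
                 gene_set = rownames(L)[idx]),
            class = "confound_model")
}

#' @export
print.confound_model <- function(x, ...) {
  cat("Confound model:", length(x$gene_set), "gene-set members,",
      length(x$selected), "component(s) selected",
      if (length(x$selected)) paste0("(", paste(x$selected, collapse = ", "),
                                     ")") else "", "\n")
  invisible(x)
}

#' Subtract gene-set-associated components from the expression matrix
#'
#' Reconstructs the data captured by the selected components,
#' `sum_{j in S} P_j L_j'` with the gene loadings scaled per gene by the SAM
#' weights (so only highly weighted genes contribute), and subtracts it from
#' `E`. With no selected components `E` is returned unchanged with a message.
#'
#' @param E Log-scale cells x genes matrix.
#' @param embedding The `sam_pca` whose components/loadings are removed.
#' @param w Gene weight vector (length `ncol(E)`); pass `rep(1, ncol(E))` for
#'   unweighted removal.
#' @param model A `confound_model` from [pc_gene_association()].
#' @return The residual matrix `E_removed` (may contain negative values).
#' @export
remove_confound <- function(E, embedding, w, model) {
  stopifnot_matrix(E)
  stopifnot(inherits(model, "confound_model"))
  S <- model$selected
  if (!length(S)) {
    message("no components selected; returning E unchanged")
    return(E)
  }
  P <- embedding$scores
  L <- embedding$loadings
  if (max(S) > ncol(P))
    stop("selected components exceed those available", call. = FALSE)
  if (nrow(L) != ncol(E) || nrow(P) != nrow(E))
    stop("embedding dimensions do not match E", call. = FALSE)
  recon <- P[, S, drop = FALSE] %*% t(L[, S, drop = FALSE])
  recon <- sweep(recon, 2, as.numeric(w), "*")
  E - recon
}

#' Re-run the manifold reconstruction after confound removal
#'
#' Two-stage workflow: fit SAM on `E`, score each component's association with
#' the gene set, subtract the selected components (loadings scaled by the
#' first fit's gene weights) from `E`, and fit SAM again on the residual. The
#' second fit computes spatial dispersions from the original `E`, because the
#' residual may contain negative values for which dispersion is ill-defined.
#'
#' @param E Filtered, log-scale cells x genes matrix.
#' @param gene_set Character vector of confounding gene ids (e.g. cell-cycle
#'   genes).
#' @param n_sd Component-selection threshold in SDs (default 2).
#' @param ... Parameters passed to both [run_sam()] calls.
#' @return List of class `sam_removal`: `fit_before`, `fit_after`, `model`,
#'   `E_removed`.
#' @export
rerun_with_removal <- function(E, gene_set, n_sd = 2, ...) {
  fit1 <- run_sam(E, ...)
  model <- pc_gene_association(fit1$pca, gene_set, n_sd = n_sd)
  if (!length(model$selected)) {
    message("no components associated with the gene set; re-using plain fit")
    return(structure(list(fit_before = fit1, fit_after = fit1, model = model,
                          E_removed = E), class = "sam_removal"))
  }
  E_removed <- remove_confound(E, fit1$pca, fit1$weights, model)
  fit2 <- run_sam(E_removed, dispersion_input = E, ...)
  structure(list(fit_before = fit1, fit_after = fit2, model = model,
                 E_removed = E_removed),
            class = "sam_removal")
}
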