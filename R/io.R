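#' Export genes ranked by weight for gene set enrichment analysis
#'
#' Writes a two-column tab-delimited `.rnk` file (gene id, weight) sorted by
#' descending weight with ties broken lexicographically by gene id — the
#' pre-ranked input format consumed by GSEA.
#'
#' @param w Named weight vector, or a `sam_fit`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_ranked_genes <- function(w, path) {
  if (inherits(w, "sam_fit")) w <- w$weights
  if (is.null(names(w))) stop("weights must be named by gene id", call. = FALSE)
  ord <- order(-as.numeric(w), names(w))
  df <- data.frame(gene = names(w)[ord], weight = as.numeric(w)[ord])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a ranked-gene file back into a weight vector
#'
#' @param path A `.rnk` file written by [export_ranked_genes()].
#' @return Named numeric vector in file order.
#' @export
read_ranked_genes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("gene", "weight"))
  setNames(df$weight, df$gene)
}

#' Save a SAM fit to a directory
#'
#' Writes `adjacency.mtx` (directed 0/1 Matrix Market), `weights.tsv`
#' (gene, fano, weight; descending weight), `embedding.tsv` (eigenvalue-scaled
#' PCs), `trace.tsv` and `result.json` (parameters, convergence, saturation
#' level).
#'
#' @param fit A `sam_fit`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_sam_result <- function(fit, dir) {
  stopifnot(inherits(fit, "sam_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(as_adjacency(fit$graph), "CsparseMatrix"),
                  file.path(dir, "adjacency.mtx"))
  write.table(weight_table(fit), file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emb <- data.frame(cell = rownames(fit$pca$scaled), fit$pca$scaled,
                    check.names = FALSE)
  colnames(emb) <- c("cell", paste0("PC", seq_len(ncol(fit$pca$scaled))))
  write.table(emb, file.path(dir, "embedding.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fit$trace, file.path(dir, "trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- c(fit$params,
            list(converged = fit$converged, iterations = fit$iterations,
                 z = attr(fit$weights, "z"), n = fit$graph$n,
                 m = length(fit$weights)))
  jsonlite::write_json(meta, file.path(dir, "result.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Load the serialized parts of a SAM fit
#'
#' Inverts [save_sam_result()] for the serialized components. Discrete parts
#' (graph, parameters, trace iterations) round-trip losslessly; floating
#' point tables round-trip to the precision written.
#'
#' @param dir Directory written by [save_sam_result()].
#' @return List with `graph`, `weights` (data.frame), `embedding` (matrix),
#'   `trace`, `meta`.
#' @export
load_sam_result <- function(dir) {
  need <- c("adjacency.mtx", "weights.tsv", "embedding.tsv", "trace.tsv",
            "result.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("result directory is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  graph <- graph_from_adjacency(Matrix::readMM(file.path(dir,
                                                         "adjacency.mtx")))
  weights <- read.delim(file.path(dir, "weights.tsv"))
  embdf <- read.delim(file.path(dir, "embedding.tsv"), check.names = FALSE)
  emb <- as.matrix(embdf[, -1, drop = FALSE])
  rownames(emb) <- embdf[[1]]
  trace <- read.delim(file.path(dir, "trace.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "result.json"),
                              simplifyVector = TRUE)
  list(graph = graph, weights = weights, embedding = emb, trace = trace,
       meta = meta)
}

#' Write a synthetic dataset to disk
#'
#' Emits `matrix.mtx` (cells x genes, sparse), `cells.txt`, `genes.txt`,
#' `labels.tsv` (cell, label) and, when present, `markers.txt` and
#' `confound_genes.txt`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_synthetic <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix::Matrix(ds$E, sparse = TRUE), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(ds$E), file.path(dir, "cells.txt"))
  writeLines(colnames(ds$E), file.path(dir, "genes.txt"))
  write.table(data.frame(cell = rownames(ds$E), label = ds$labels),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(ds$markers))
    writeLines(unlist(ds$markers), file.path(dir, "markers.txt"))
  if (!is.null(ds$confound_genes))
    writeLines(ds$confound_genes, file.path(dir, "confound_genes.txt"))
  invisible(dir)
}
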