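#' Load an expression matrix from disk
#'
#' Reads a cells x genes expression matrix either from a Matrix Market sparse
#' triplet file with separate newline-delimited cell and gene label files, or
#' from a dense delimited text file whose header row holds gene ids and whose
#' first column holds cell ids.
#'
#' @param path Path to the matrix file.
#' @param format `"mtx"` for Matrix Market plus label files, `"dense"` for
#'   delimited text, or `"auto"` (default) to decide from the file extension.
#' @param cells_path,genes_path Label files (one id per line) for the `"mtx"`
#'   format; ignored for dense input.
#' @param cells_as Orientation of the stored matrix: `"rows"` (default) if
#'   cells are rows, `"cols"` to transpose on load.
#' @param already_logged Set `TRUE` if the stored values are already
#'   log-transformed; recorded so [log_transform()] can refuse to double-log.
#' @param sep Field separator for dense input (default tab).
#'
#' @return A numeric cells x genes matrix with cell ids as rownames, gene ids
#'   as colnames and an `"already_logged"` attribute.
#' @export
load_expression <- function(path, format = c("auto", "mtx", "dense"),
                            cells_path = NULL, genes_path = NULL,
                            cells_as = c("rows", "cols"),
                            already_logged = FALSE, sep = "\t") {
  format <- match.arg(format)
  cells_as <- match.arg(cells_as)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"

  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    if (is.null(cells_path) || is.null(genes_path))
      stop("mtx input requires `cells_path` and `genes_path` label files",
           call. = FALSE)
    cells <- readLines(cells_path)
    genes <- readLines(genes_path)
    if (cells_as == "cols") M <- t(M)
    if (length(cells) != nrow(M))
      stop("cell label file has ", length(cells), " ids for ", nrow(M),
           " matrix rows", call. = FALSE)
    if (length(genes) != ncol(M))
      stop("gene label file has ", length(genes), " ids for ", ncol(M),
           " matrix columns", call. = FALSE)
    dimnames(M) <- list(cells, genes)
  } else {
    df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                     check.names = FALSE)
    M <- as.matrix(df)
    if (!is.numeric(M)) stop("dense input is not numeric", call. = FALSE)
    if (cells_as == "cols") M <- t(M)
  }
  if (anyDuplicated(rownames(M))) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(colnames(M))) stop("duplicate gene ids", call. = FALSE)
  check_finite(M)
  if (any(M < 0)) stop("expression values must be nonnegative", call. = FALSE)
  attr(M, "already_logged") <- isTRUE(already_logged)
  M
}

#' Log-transform raw expression values
#'
#' Entrywise `x -> log_base(x + pseudocount)`, the standard `log2(x + 1)`
#' transform by default. Zeros map to zero. Refuses input flagged as already
#' log-transformed.
#'
#' @param raw Nonnegative numeric matrix (cells x genes).
#' @param base Logarithm base (default 2).
#' @param pseudocount Added before the log (default 1).
#' @return The transformed matrix, flagged with `already_logged = TRUE`.
#' @export
log_transform <- function(raw, base = 2, pseudocount = 1) {
  stopifnot_matrix(raw, "raw")
  if (isTRUE(attr(raw, "already_logged")))
    stop("input is flagged as already log-transformed", call. = FALSE)
  if (any(raw < 0)) stop("raw expression must be nonnegative", call. = FALSE)
  E <- log(raw + pseudocount, base = base)
  attributes(E) <- attributes(raw)[c("dim", "dimnames")]
  attr(E, "already_logged") <- TRUE
  E
}

#' Drop genes detected in too few or too many cells
#'
#' A gene is kept iff the fraction of cells in which it is expressed (log
#' expression strictly greater than `expr_threshold`) lies in the closed
#' interval `[min_frac, max_frac]`. Genes outside this band lack statistical
#' power (near-absent) or carry no contrast (near-ubiquitous).
#'
#' @param E Log-scale cells x genes matrix.
#' @param expr_threshold Expression above this counts as "expressed"
#'   (default 1, i.e. `log2(x+1) > 1`).
#' @param min_frac,max_frac Closed prevalence interval (defaults 0.01, 0.99).
#' @return `E` restricted to the kept genes, column order preserved.
#' @export
filter_genes <- function(E, expr_threshold = 1, min_frac = 0.01,
                         max_frac = 0.99) {
  stopifnot_matrix(E)
  stopifnot(min_frac >= 0, max_frac <= 1, min_frac < max_frac)
  frac <- colMeans(E > expr_threshold)
  keep <- frac >= min_frac & frac <= max_frac
  if (!any(keep))
    stop("no informative genes: all genes fail the prevalence filter",
         call. = FALSE)
  out <- E[, keep, drop = FALSE]
  attr(out, "already_logged") <- attr(E, "already_logged")
  out
}

#' Zero out expression below the noise floor
#'
#' Entries strictly below `floor` are set to exactly 0 to suppress technical
#' noise near the molecular detection limit; entries at or above the floor are
#' untouched.
#'
#' @param E Log-scale cells x genes matrix.
#' @param floor Noise floor on the log scale (default 1).
#' @return Thresholded matrix.
#' @export
threshold_noise <- function(E, floor = 1) {
  stopifnot_matrix(E)
  E[E < floor] <- 0
  E
}

#' Standardize or L2-normalize an expression matrix
#'
#' `mode = "standardized"` scales every gene column to zero mean and unit
#' population variance (1/n convention); constant columns become all zeros.
#' `mode = "l2"` scales every cell row to unit Euclidean norm; all-zero rows
#' stay zero. Standardization suits large sparse datasets with many
#' subpopulations, L2 normalization smaller datasets with few.
#'
#' @param E Log-scale cells x genes matrix.
#' @param mode `"standardized"` or `"l2"`.
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(E, mode = c("standardized", "l2")) {
  mode <- match.arg(mode)
  stopifnot_matrix(E)
  if (mode == "standardized") {
    mu <- colMeans(E)
    v <- col_pop_var(E)
    s <- sqrt(v)
    out <- sweep(E, 2, mu, "-")
    nz <- s > 0
    out[, nz] <- sweep(out[, nz, drop = FALSE], 2, s[nz], "/")
    out[, !nz] <- 0
  } else {
    nrm <- sqrt(rowSums(E^2))
    out <- E
    nz <- nrm > 0
    out[nz, ] <- E[nz, , drop = FALSE] / nrm[nz]
  }
  attr(out, "norm_mode") <- mode
  out
}

#' Standard preprocessing: noise thresholding then prevalence filtering
#'
#' Convenience wrapper applying [threshold_noise()] followed by
#' [filter_genes()] with a shared threshold, the order in which the two steps
#' commute.
#'
#' @inheritParams filter_genes
#' @param floor Shared noise floor / expression threshold (default 1).
#' @return Filtered, thresholded matrix ready for [run_sam()].
#' @export
preprocess_expression <- function(E, floor = 1, min_frac = 0.01,
                                  max_frac = 0.99) {
  filter_genes(threshold_noise(E, floor = floor), expr_threshold = floor,
               min_frac = min_frac, max_frac = max_frac)
}
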