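#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rgamma rpois runif rnorm sd quantile setNames
#' @importFrom utils head read.delim write.table
#' @importFrom methods as
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Population (1/n) column means and variances.
col_pop_var <- function(x) {
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}

stopifnot_matrix <- function(E, arg = "E") {
  if (!is.matrix(E) || !is.numeric(E))
    stop("`", arg, "` must be a numeric matrix (cells x genes)", call. = FALSE)
}

check_finite <- function(E, arg = "E") {
  if (!all(is.finite(E)))
    stop("`", arg, "` contains non-finite values", call. = FALSE)
}

gene_ids <- function(E) {
  if (!is.null(colnames(E))) colnames(E) else paste0("g", seq_len(ncol(E)))
}

cell_ids <- function(E) {
  if (!is.null(rownames(E))) rownames(E) else paste0("c", seq_len(nrow(E)))
}
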