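#' Run code with a local, restored RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a seed to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Moore-Penrose pseudoinverse via SVD
#' @param x numeric matrix
#' @param tol singular values below `tol * max(sv)` are treated as zero
#' @return matrix, the pseudoinverse of `x`
#' @keywords internal
pinv <- function(x, tol = sqrt(.Machine$double.eps)) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Gram force per minute expressed in newtons per second
#' @keywords internal
GRAM_FORCE_N <- 9.80665e-3
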