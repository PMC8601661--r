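#' @keywords internal
"_PACKAGE"

## Internal numerical helpers shared across modules.

#' Evaluate an expression under a fixed RNG state, restoring the caller's state
#'
#' All stochastic routines in the package funnel their draws through this
#' helper so that a given seed yields bit-identical output and the caller's
#' global random state is left untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Moore-Penrose pseudoinverse via SVD
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return the pseudoinverse of `A`.
#' @keywords internal
pinv <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (any(dim(A) == 0L)) return(t(A))
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Column-standardize a matrix (mean 0, sd 1); zero-variance columns -> 0.
standardize_cols <- function(M) {
  M <- sweep(M, 2, colMeans(M), "-")
  sds <- sqrt(colSums(M^2) / (nrow(M) - 1))
  sds[sds == 0] <- Inf
  sweep(M, 2, sds, "/")
}

## Gamma-variate hemodynamic kernel sampled at `times` (s), peak-normalized.
## shape/scale default to a ~2 s rise consistent with slow blood-volume
## responses that peak inside the 3-11 s averaging window.
hemodynamic_kernel <- function(times, shape = 3, scale = 1) {
  h <- stats::dgamma(times, shape = shape, scale = scale)
  if (max(h) > 0) h <- h / max(h)
  h
}
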