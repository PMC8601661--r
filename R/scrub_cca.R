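## Denoising part I: canonical-correlation scrubbing. Motion and other
## global artifacts drive voxels both inside and outside cortex, and the
## animals move more during some sound categories, so artifact timecourses
## are partially sound-locked. Sound-driven cortical signal, however, is
## reliable across repetitions, while artifact amplitude varies from trial
## to trial. The scrub therefore fits canonical components on the residual
## activity after removing trial-averaged responses (where no sound-locked
## signal survives), and then projects the identified shared timecourses out
## of the full data - removing both the trial-varying and the sound-locked
## part of the artifact while leaving reliable responses intact.

## Flatten a trial dataset to a (trials*T) x voxels matrix; rows ordered by
## trial, time-within-trial fastest.
flatten_time <- function(dataset, trials = NULL) {
  d <- dataset$data
  if (!is.null(trials)) d <- d[, trials, , drop = FALSE]
  m <- aperm(d, c(3, 2, 1))
  dim(m) <- c(dim(d)[3] * dim(d)[2], dim(d)[1])
  m
}

## Inverse of flatten_time for the full dataset.
unflatten_time <- function(M, dataset) {
  d <- dataset$data
  a <- array(M, dim = c(dim(d)[3], dim(d)[2], dim(d)[1]))
  aperm(a, c(3, 2, 1))
}

#' Residual activity after removing trial-averaged responses
#'
#' For each voxel and sound, subtracts the across-repetition mean timecourse
#' from each trial of that sound, then concatenates the residual trials over
#' time. Sounds with a single repetition carry no residual information and
#' are excluded with a warning.
#'
#' @param dataset a `trial_dataset`.
#' @param voxels optional integer vector restricting the voxel set.
#' @return list with `residuals` ((kept trials * T) x voxels matrix),
#'   `trials` (kept trial indices, in concatenation order).
#' @export
trial_residuals <- function(dataset, voxels = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  tab <- dataset$trial_table
  reps_per_sound <- table(tab$sound)
  multi <- as.integer(names(reps_per_sound)[reps_per_sound >= 2])
  if (length(multi) < length(reps_per_sound))
    warning(length(reps_per_sound) - length(multi),
            " single-repetition sound(s) excluded from residuals")
  if (length(multi) == 0) stop("need >= 2 repetitions for at least one sound")
  keep <- which(tab$sound %in% multi)
  d <- dataset$data
  if (is.null(voxels)) voxels <- seq_len(dim(d)[1])
  d <- d[voxels, keep, , drop = FALSE]
  sound_of <- tab$sound[keep]
  for (s in unique(sound_of)) {
    idx <- which(sound_of == s)
    avg <- apply(d[, idx, , drop = FALSE], c(1, 3), mean)
    for (j in idx) d[, j, ] <- d[, j, ] - avg
  }
  m <- aperm(d, c(3, 2, 1))
  dim(m) <- c(dim(d)[3] * dim(d)[2], dim(d)[1])
  list(residuals = m, trials = keep)
}

#' Canonical noise components shared between two voxel sets
#'
#' Ridge-regularized canonical correlation analysis between in-cortex and
#' out-of-cortex residual timecourses. Each side is whitened on its retained
#' subspace with covariance shrinkage (`shrinkage` times the mean
#' eigenvalue added to the diagonal), and the canonical structure is the SVD
#' of the whitened cross-covariance. The returned basis lives on the
#' out-of-cortex side, which by construction cannot contain cortical
#' stimulus responses.
#'
#' @param in_res,out_res residual matrices sharing the time axis (rows),
#'   e.g. from [trial_residuals()] on in- and out-of-cortex voxels.
#' @param k number of canonical components to keep (default 20).
#' @param shrinkage ridge fraction of the mean covariance eigenvalue.
#' @return object of class `noise_basis`: `timecourses` (time x k,
#'   unit-norm residual variates), `weights_out` (out-voxels x k spatial
#'   filters), `cancor` (descending canonical correlations), `k`.
#' @export
fit_noise_basis <- function(in_res, out_res, k = 20, shrinkage = 1e-3) {
  stopifnot(nrow(in_res) == nrow(out_res))
  n <- nrow(in_res)
  if (k == 0)
    return(structure(list(timecourses = matrix(0, n, 0),
                          weights_out = matrix(0, ncol(out_res), 0),
                          cancor = numeric(0), k = 0L,
                          out_center = colMeans(out_res)),
                     class = "noise_basis"))
  X <- sweep(in_res, 2, colMeans(in_res), "-")
  Y <- sweep(out_res, 2, colMeans(out_res), "-")
  wh <- function(M) {
    s <- svd(M, nu = 0)
    ev <- s$d^2 / (nrow(M) - 1)
    keep <- ev > 1e-12 * max(ev)
    lam <- shrinkage * mean(ev[keep])
    ## scores with (regularized) unit variance per retained direction
    list(V = s$v[, keep, drop = FALSE],
         scale = 1 / sqrt(ev[keep] + lam))
  }
  wx <- wh(X); wy <- wh(Y)
  Zx <- X %*% sweep(wx$V, 2, wx$scale, "*")
  Zy <- Y %*% sweep(wy$V, 2, wy$scale, "*")
  kk <- min(k, ncol(Zx), ncol(Zy))
  if (kk < k)
    message("rank deficiency: basis reduced from ", k, " to ", kk,
            " components")
  cs <- svd(crossprod(Zx, Zy) / (n - 1))
  rho <- pmin(pmax(cs$d[seq_len(kk)], 0), 1)
  weights_out <- sweep(wy$V, 2, wy$scale, "*") %*% cs$v[, seq_len(kk), drop = FALSE]
  tc <- Y %*% weights_out
  nrm <- sqrt(colSums(tc^2)); nrm[nrm == 0] <- 1
  tc <- sweep(tc, 2, nrm, "/")
  structure(list(timecourses = tc, weights_out = weights_out,
                 cancor = rho, k = kk,
                 out_center = colMeans(out_res)),
            class = "noise_basis")
}

#' Project canonical noise components out of a dataset
#'
#' Applies the out-of-cortex spatial filters of a [fit_noise_basis()] fit to
#' the full (non-residualized) out-of-cortex data, yielding noise
#' timecourses defined on every trial, and subtracts each voxel's
#' least-squares projection onto their span. Because the filters were fit on
#' trial residuals, reliable sound-locked cortical signal does not load on
#' them, while both the trial-varying and the sound-locked portion of the
#' shared artifact are removed.
#'
#' @param dataset a `trial_dataset`.
#' @param basis a `noise_basis`.
#' @param out_voxels integer indices of the out-of-cortex voxels the basis
#'   was fit on (default: `!geometry$cortex_mask`).
#' @return the dataset with the noise components removed (dimensions
#'   unchanged).
#' @export
remove_noise_components <- function(dataset, basis, out_voxels = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"), inherits(basis, "noise_basis"))
  if (basis$k == 0) return(dataset)
  if (is.null(out_voxels)) out_voxels <- which(!dataset$geometry$cortex_mask)
  stopifnot(length(out_voxels) == nrow(basis$weights_out))
  M <- flatten_time(dataset)
  Z <- sweep(M[, out_voxels, drop = FALSE], 2, basis$out_center, "-") %*%
    basis$weights_out
  Z <- sweep(Z, 2, colMeans(Z), "-")
  Q <- qr.Q(qr(Z))
  M <- M - Q %*% crossprod(Q, M)
  dataset$data <- unflatten_time(M, dataset)
  dataset
}

#' Fit and apply the CCA scrub in one call
#'
#' Convenience wrapper: computes trial residuals for in- and out-of-cortex
#' voxels, fits the canonical noise basis, and removes it from the full
#' dataset.
#'
#' @inheritParams fit_noise_basis
#' @param dataset a `trial_dataset` with geometry.
#' @return list with `dataset` (scrubbed) and `basis`.
#' @export
scrub_dataset <- function(dataset, k = 20, shrinkage = 1e-3) {
  mask <- dataset$geometry$cortex_mask
  in_res <- trial_residuals(dataset, voxels = which(mask))
  out_res <- trial_residuals(dataset, voxels = which(!mask))
  basis <- fit_noise_basis(in_res$residuals, out_res$residuals,
                           k = k, shrinkage = shrinkage)
  list(dataset = remove_noise_components(dataset, basis), basis = basis)
}
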