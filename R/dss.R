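## Denoising part II: reliability-biased component extraction (a variant of
## denoising source separation / joint decorrelation). Each repetition x
## slice data matrix is whitened so that all response directions have equal
## variance; whitened matrices are averaged across repetitions (enhancing
## repetition-reliable structure) and concatenated across slices along the
## voxel dimension (enhancing slice-shared structure, since slices come from
## different sessions with independent noise); PCA of the concatenation then
## yields components ordered by cross-repetition/cross-slice reliability
## rather than raw variance. Projecting the data onto the top N "reliable
## components" denoises it.

#' ZCA whitening of a time x voxels matrix
#'
#' Centers columns and rescales the data so the covariance is the identity
#' on the retained subspace (directions with singular value below
#' `tol * max` are dropped; zero-variance voxels are handled the same way).
#'
#' @param M time x voxels matrix with more rows than retained rank.
#' @param tol relative singular-value cutoff (default 1e-6).
#' @return whitened matrix of the same dimensions.
#' @export
whiten <- function(M, tol = 1e-6) {
  M <- as.matrix(M)
  M <- sweep(M, 2, colMeans(M), "-")
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  sqrt(nrow(M) - 1) * s$u[, keep, drop = FALSE] %*% t(s$v[, keep, drop = FALSE])
}

## Per (repetition, slice) concatenated-timecourse matrices restricted to
## in-cortex voxels: mats[[rep]][[slice]] is (n_sel_sounds * T) x voxels,
## rows ordered sound-major (all timepoints of sound 1, then sound 2, ...).
rep_slice_matrices <- function(dataset, sounds = NULL, reps = NULL) {
  tab <- dataset$trial_table
  geom <- dataset$geometry
  if (is.null(sounds)) sounds <- sort(unique(tab$sound))
  if (is.null(reps)) reps <- sort(unique(tab$rep))
  slices <- sort(unique(geom$slice_id[geom$cortex_mask]))
  n_t <- dim(dataset$data)[3]
  lapply(reps, function(r) {
    trial_of <- vapply(sounds, function(s) {
      w <- which(tab$sound == s & tab$rep == r)
      if (length(w) == 0) NA_integer_ else w[1]
    }, integer(1))
    if (anyNA(trial_of))
      stop("missing repetitions: sound(s) ",
           paste(sounds[is.na(trial_of)], collapse = ","), " for rep ", r)
    lapply(slices, function(s) {
      vox <- which(geom$cortex_mask & geom$slice_id == s)
      d <- dataset$data[vox, trial_of, , drop = FALSE]
      m <- aperm(d, c(3, 2, 1))
      dim(m) <- c(n_t * length(trial_of), length(vox))
      m
    })
  })
}

## Repetition-averaged concatenated data matrix over all in-cortex voxels:
## (n_sel_sounds * T) x voxels, slices side by side in voxel order.
concat_data_matrix <- function(dataset, sounds = NULL, reps = NULL) {
  mats <- rep_slice_matrices(dataset, sounds = sounds, reps = reps)
  n_slices <- length(mats[[1]])
  do.call(cbind, lapply(seq_len(n_slices), function(s) {
    Reduce(`+`, lapply(mats, `[[`, s)) / length(mats)
  }))
}

#' Extract reliable components from repetition x slice matrices
#'
#' Whitens each matrix, averages the whitened matrices across repetitions,
#' concatenates the repetition averages across slices along the voxel
#' dimension, and takes the top-N principal components over time. Because
#' every input was whitened, the leading components are those most reliable
#' across repetitions and slices, not those with the highest raw variance.
#'
#' @param mats list (over repetitions) of lists (over slices) of
#'   time x voxel matrices sharing the time axis, as built by the package
#'   from a `trial_dataset` (in-cortex voxels only).
#' @param N number of components to return (truncated to the data rank
#'   with a warning).
#' @return object of class `reliable_components`: `R` (time x N, orthonormal
#'   columns), `d` (singular values), `N`.
#' @export
fit_reliable_components <- function(mats, N) {
  stopifnot(length(mats) >= 2)
  n_slices <- length(mats[[1]])
  conc <- do.call(cbind, lapply(seq_len(n_slices), function(s) {
    wh <- lapply(mats, function(m) whiten(m[[s]]))
    Reduce(`+`, wh) / length(wh)
  }))
  s <- svd(conc, nv = 0)
  rank_ <- sum(s$d > 1e-10 * max(s$d))
  if (N > rank_) {
    warning("N = ", N, " exceeds data rank ", rank_, "; truncated")
    N <- rank_
  }
  structure(list(R = s$u[, seq_len(N), drop = FALSE],
                 d = s$d, N = N),
            class = "reliable_components")
}

#' Project a data matrix onto reliable components
#'
#' `D_denoised = R R^+ D`: the least-squares projection of each voxel's
#' timecourse onto the span of the reliable components.
#'
#' @param D time x voxels data matrix (time axis matching `R`).
#' @param R a `reliable_components` object, or a time x N matrix.
#' @return denoised matrix of the same dimensions as `D` (rank <= N).
#' @export
project_denoise <- function(D, R) {
  Rm <- if (inherits(R, "reliable_components")) R$R else as.matrix(R)
  if (ncol(Rm) == 0) return(D * 0)
  stopifnot(nrow(Rm) == nrow(D))
  Rm %*% (pinv(Rm) %*% D)
}

#' Fit reliable components directly from a trial dataset
#'
#' @param dataset a `trial_dataset` in percent-signal-change units.
#' @param N component count (default 8).
#' @param sounds,reps optional subsets.
#' @return a `reliable_components` object.
#' @export
dss_fit <- function(dataset, N = 8, sounds = NULL, reps = NULL) {
  fit_reliable_components(rep_slice_matrices(dataset, sounds, reps), N)
}

#' Denoise a dataset's concatenated responses with reliable components
#'
#' @param dataset a `trial_dataset`.
#' @param rc a `reliable_components` fit on the same sound set.
#' @param sounds,reps optional subsets (must match the fit's time axis).
#' @return denoised (sounds*T) x voxels matrix.
#' @export
dss_denoise <- function(dataset, rc, sounds = NULL, reps = NULL) {
  D <- concat_data_matrix(dataset, sounds = sounds, reps = reps)
  project_denoise(D, rc)
}

## Stratified train/test split of natural/synthetic pairs: pairs stay
## together; assignment balanced by category, round-robin within category.
train_test_split_pairs <- function(sound_table, train_frac = 0.75, seed = 1) {
  pairs <- unique(sound_table$pair)
  cat_of <- sound_table$category[match(pairs, sound_table$pair)]
  with_seed(seed, {
    test_pairs <- integer(0)
    for (cat in unique(cat_of)) {
      p <- sample(pairs[cat_of == cat])
      n_test <- max(1, round((1 - train_frac) * length(p)))
      test_pairs <- c(test_pairs, p[seq_len(n_test)])
    }
    train_pairs <- setdiff(pairs, test_pairs)
    list(train = sort(sound_table$sound[sound_table$pair %in% train_pairs]),
         test = sort(sound_table$sound[sound_table$pair %in% test_pairs]))
  })
}

## Windowed per-sound responses from a concatenated (sounds*T) x voxels
## matrix: voxels x sounds.
window_average_concat <- function(M, n_sounds, timing, window = c(3, 11)) {
  n_t <- nrow(M) / n_sounds
  tt <- seq(0, n_t - 1) * timing$dt
  post <- tt - timing$baseline
  win <- which(post >= window[1] & post < window[2])
  t(sapply(seq_len(n_sounds), function(s) {
    rows <- (s - 1) * n_t + win
    colMeans(M[rows, , drop = FALSE])
  }))
}

#' Cross-validated component-count selection for DSS denoising
#'
#' Splits the sound set into training and test pairs (natural and matched
#' synthetic sounds always on the same side, balanced by category). For
#' each candidate N: fits reliable components on the training sounds,
#' computes voxel weights `W = R_train^+ D_train`, and denoises the
#' held-out test responses via `R_test = D_test W^+`, `D_test_denoised =
#' R_test W` - so no component structure is refit on test data. Reports the
#' per-voxel split-half correlation (odd vs even repetitions, windowed
#' responses to test sounds) before denoising, after denoising one split,
#' after denoising both, and the upper bound `sqrt(split-half reliability)`.
#'
#' @param dataset a `trial_dataset` in percent-signal-change units.
#' @param N_range candidate component counts (default 1:16).
#' @param train_frac fraction of pairs used for training (default 0.75).
#' @param window averaging window, seconds post-onset.
#' @param seed seed for the stratified split.
#' @return data.frame with one row per N: median split-half correlation
#'   raw, denoised-one-split, denoised-both, and the median upper bound;
#'   plus attribute `"per_voxel"` holding the per-voxel correlations at
#'   each N.
#' @export
crossval_component_count <- function(dataset, N_range = 1:16,
                                     train_frac = 0.75, window = c(3, 11),
                                     seed = 1) {
  split <- train_test_split_pairs(dataset$sound_table, train_frac, seed)
  reps <- sort(unique(dataset$trial_table$rep))
  odd <- reps[reps %% 2 == 1]; even <- reps[reps %% 2 == 0]
  stopifnot(length(odd) > 0, length(even) > 0)
  Nmax <- max(N_range)
  rc <- fit_reliable_components(
    rep_slice_matrices(dataset, sounds = split$train), Nmax)
  if (rc$N < Nmax) N_range <- N_range[N_range <= rc$N]
  D_train <- concat_data_matrix(dataset, sounds = split$train)
  D_odd <- concat_data_matrix(dataset, sounds = split$test, reps = odd)
  D_even <- concat_data_matrix(dataset, sounds = split$test, reps = even)
  n_test <- length(split$test)
  timing <- dataset$timing

  resp_odd <- window_average_concat(D_odd, n_test, timing, window)
  resp_even <- window_average_concat(D_even, n_test, timing, window)
  corr_vox <- function(A, B)
    sapply(seq_len(ncol(A)), function(v) stats::cor(A[, v], B[, v]))
  raw <- corr_vox(resp_odd, resp_even)
  upper <- sqrt(pmax(raw, 0))

  per_voxel <- list()
  out <- data.frame(N = N_range, raw = NA_real_, denoised_one = NA_real_,
                    denoised_both = NA_real_, upper = NA_real_)
  for (i in seq_along(N_range)) {
    N <- N_range[i]
    W <- pinv(rc$R[, seq_len(N), drop = FALSE]) %*% D_train
    Wp <- pinv(W)
    den_odd <- (D_odd %*% Wp) %*% W
    den_even <- (D_even %*% Wp) %*% W
    r_odd <- window_average_concat(den_odd, n_test, timing, window)
    r_even <- window_average_concat(den_even, n_test, timing, window)
    one <- corr_vox(r_odd, resp_even)
    both <- corr_vox(r_odd, r_even)
    out$raw[i] <- stats::median(raw, na.rm = TRUE)
    out$denoised_one[i] <- stats::median(one, na.rm = TRUE)
    out$denoised_both[i] <- stats::median(both, na.rm = TRUE)
    out$upper[i] <- stats::median(upper, na.rm = TRUE)
    per_voxel[[as.character(N)]] <-
      list(raw = raw, denoised_one = one, denoised_both = both, upper = upper)
  }
  attr(out, "per_voxel") <- per_voxel
  attr(out, "split") <- split
  out
}
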