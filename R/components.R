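## Voxel component decomposition and cross-species prediction.
##
## The decomposition models each voxel as a weighted sum of a small number
## of shared response patterns. Like ICA it exploits non-Gaussianity: a
## rotation of the PCA-reduced data is sought that minimizes the entropy of
## the component weight distributions across voxels (the Gaussian has
## maximal entropy at fixed variance, so minimum-entropy weights are
## maximally non-Gaussian). With tens of thousands of voxels the entropy can
## be estimated with a simple histogram, which is what distinguishes this
## estimator from kurtosis- or negentropy-approximation ICA.

## Histogram entropy of a weight vector: 100 equal-width bins spanning the
## robust (1st-99th percentile) range, add-one smoothing.
hist_entropy <- function(w, bins = 100) {
  rng <- stats::quantile(w, c(0.01, 0.99), names = FALSE, type = 7)
  if (rng[2] <= rng[1]) return(0)
  b <- pmin(pmax(floor((w - rng[1]) / (rng[2] - rng[1]) * bins), 0), bins - 1)
  counts <- tabulate(b + 1L, nbins = bins) + 1
  p <- counts / sum(counts)
  -sum(p * log(p))
}

## Givens rotation of columns (i, j) by angle theta.
rotate_pair <- function(W, i, j, theta) {
  ci <- W[, i]; cj <- W[, j]
  W[, i] <- ci * cos(theta) + cj * sin(theta)
  W[, j] <- -ci * sin(theta) + cj * cos(theta)
  W
}

## One full optimization run from a starting rotation: Jacobi sweeps over
## column pairs, golden-section line search per pair.
entropy_rotation_run <- function(W0, Q, bins, max_sweeps = 30, tol = 1e-6) {
  W <- W0 %*% Q
  K <- ncol(W)
  ent <- vapply(seq_len(K), function(k) hist_entropy(W[, k], bins), 0)
  for (sweep in seq_len(max_sweeps)) {
    improved <- 0
    for (i in seq_len(K - 1)) for (j in seq((i + 1), K)) {
      obj <- function(theta) {
        ci <- W[, i] * cos(theta) + W[, j] * sin(theta)
        cj <- -W[, i] * sin(theta) + W[, j] * cos(theta)
        hist_entropy(ci, bins) + hist_entropy(cj, bins)
      }
      opt <- stats::optimize(obj, c(-pi / 4, pi / 4), tol = 1e-4)
      if (opt$objective < ent[i] + ent[j] - tol) {
        improved <- improved + (ent[i] + ent[j] - opt$objective)
        W <- rotate_pair(W, i, j, opt$minimum)
        Q <- rotate_pair(Q, i, j, opt$minimum)
        ent[i] <- hist_entropy(W[, i], bins)
        ent[j] <- hist_entropy(W[, j], bins)
      }
    }
    if (improved < tol) break
  }
  list(Q = Q, objective = sum(ent))
}

#' Histogram-entropy component decomposition of a voxel data matrix
#'
#' PCA-reduces `D` to `K` dimensions, then optimizes a K x K rotation
#' minimizing the summed histogram entropy of the K weight distributions
#' across voxels (Jacobi pairwise rotations with golden-section line
#' search, best of `n_restarts` seeded random restarts). Component weights
#' are normalized to unit RMS; each component's sign is chosen so the
#' skewness of its weights is positive; components are ordered by explained
#' variance.
#'
#' @param D voxels x features data matrix (features: time-averaged
#'   responses per sound, or concatenated timecourses). Needs many voxels
#'   (thousands) for the histogram entropy estimate.
#' @param K number of components (<= rank of `D`).
#' @param seed integer seed for the restarts.
#' @param n_restarts random rotation restarts (default 10).
#' @param bins histogram bins (default 100).
#' @return object of class `component_set`: `profiles` (features x K),
#'   `weights` (voxels x K, unit RMS), `total_variance` (per-component
#'   share, summing to 1), `objective`, `identifiable`.
#' @export
decompose <- function(D, K, seed = 1, n_restarts = 10, bins = 100) {
  D <- as.matrix(D)
  stopifnot(K >= 1, K <= min(dim(D)))
  s <- svd(D, nu = K, nv = K)
  if (s$d[K] <= 1e-12 * s$d[1]) stop("K exceeds numerical rank of D")
  W0 <- s$u                                   # voxels x K, orthonormal
  H0 <- s$v %*% diag(s$d[seq_len(K)], K, K)   # features x K
  if (K == 1) {
    Q <- diag(1)
    best <- list(Q = Q, objective = hist_entropy(W0[, 1], bins))
  } else {
    runs <- with_seed(seed, {
      lapply(seq_len(n_restarts), function(r) {
        Q0 <- if (r == 1) diag(K) else qr.Q(qr(matrix(stats::rnorm(K * K), K)))
        entropy_rotation_run(W0, Q0, bins)
      })
    })
    objs <- vapply(runs, `[[`, 0, "objective")
    best <- runs[[which.min(objs)]]
  }
  W <- W0 %*% best$Q
  H <- H0 %*% best$Q
  ## sign: positive weight skewness
  sk <- vapply(seq_len(K), function(k) {
    z <- W[, k] - mean(W[, k]); mean(z^3) / (stats::sd(W[, k])^3 + 1e-30)
  }, 0)
  flip <- ifelse(sk < 0, -1, 1)
  W <- sweep(W, 2, flip, "*"); H <- sweep(H, 2, flip, "*")
  ## unit-RMS weights; variance share per component
  rms <- sqrt(colMeans(W^2)); rms[rms == 0] <- 1
  W <- sweep(W, 2, rms, "/"); H <- sweep(H, 2, rms, "*")
  vshare <- colSums(H^2) * colMeans(W^2)
  o <- order(vshare, decreasing = TRUE)
  W <- W[, o, drop = FALSE]; H <- H[, o, drop = FALSE]
  vshare <- vshare[o] / sum(vshare)
  ## Identifiability requires non-Gaussian weights: flag solutions whose
  ## weight distributions are all indistinguishable from Gaussian (small
  ## skewness and excess kurtosis) - for such data the entropy objective is
  ## flat under rotation up to sampling noise.
  nongauss <- vapply(seq_len(K), function(k) {
    z <- (W[, k] - mean(W[, k])) / stats::sd(W[, k])
    max(abs(mean(z^3)), abs(mean(z^4) - 3))
  }, 0)
  flat <- all(nongauss < 0.5) && K > 1
  if (flat)
    warning("weight distributions are approximately Gaussian; ",
            "the entropy objective is flat and components are unidentifiable")
  structure(list(profiles = H, weights = W, total_variance = vshare,
                 objective = best$objective, identifiable = !flat,
                 K = K, seed = seed),
            class = "component_set")
}

## Closed-form ridge: fit on centered (X, y), return function(lambda) -> coef
## in the original X columns, via SVD computed once.
ridge_path <- function(X, y) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-"); yc <- y - ym
  s <- svd(Xc)
  uty <- crossprod(s$u, yc)
  function(lambda) {
    shrink <- s$d / (s$d^2 + lambda)
    beta <- s$v %*% (shrink * uty)
    list(beta = beta, intercept = ym - sum(xm * beta))
  }
}

## lambda grid: 2^-100 .. 2^100, 201 log2-spaced points.
ridge_grid <- function() 2^seq(-100, 100, by = 1)

## Assign pairs to folds (round-robin over shuffled pairs); returns fold id
## per sound, with a natural sound and its matched synthetic always in the
## same fold.
pair_folds <- function(pairs, n_folds, seed) {
  up <- unique(pairs)
  with_seed(seed, {
    up <- sample(up)
    fold_of_pair <- rep_len(seq_len(n_folds), length(up))
    fold_of_pair[match(pairs, up)]
  })
}

#' Cross-species component prediction by cross-validated ridge regression
#'
#' Predicts each target component's response profile from all source
#' component profiles using 9-fold cross-validated ridge regression, with
#' the ridge penalty selected per training fold by nested 9-fold
#' cross-validation over a 2^-100 .. 2^100 log-spaced grid. Folds contain
#' whole natural/synthetic pairs so train and test sounds never share a
#' pair. Predictions are assembled out-of-fold.
#'
#' @param source sounds x Ks matrix of source-species component profiles
#'   (or a `component_set`).
#' @param target sounds x Kt matrix of target profiles (or a
#'   `component_set`).
#' @param pairs length-sounds vector of pair identifiers.
#' @param folds number of outer (and inner) folds, default 9.
#' @param seed seed for fold assignment.
#' @return object of class `prediction_result`: `predicted` (sounds x Kt
#'   out-of-fold predictions), `nse_pred`, `explained_variance`
#'   (sign-preserving (1-NSE)^2), `lambda` (chosen penalty per outer fold x
#'   target).
#' @export
crossspecies_predict <- function(source, target, pairs, folds = 9, seed = 1) {
  X <- if (inherits(source, "component_set")) source$profiles else as.matrix(source)
  Y <- if (inherits(target, "component_set")) target$profiles else as.matrix(target)
  stopifnot(nrow(X) == nrow(Y), length(pairs) == nrow(X))
  grid <- ridge_grid()
  fold <- pair_folds(pairs, folds, seed)
  pred <- matrix(NA_real_, nrow(Y), ncol(Y))
  lam <- matrix(NA_real_, folds, ncol(Y))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(te) == 0) next
    inner_fold <- pair_folds(pairs[tr], folds, seed + f)
    for (k in seq_len(ncol(Y))) {
      ## nested CV error per lambda
      err <- numeric(length(grid))
      for (g in seq_len(folds)) {
        itr <- tr[inner_fold != g]; ite <- tr[inner_fold == g]
        if (length(ite) == 0 || length(itr) < 2) next
        rp <- ridge_path(X[itr, , drop = FALSE], Y[itr, k])
        for (li in seq_along(grid)) {
          fit <- rp(grid[li])
          e <- Y[ite, k] - (X[ite, , drop = FALSE] %*% fit$beta + fit$intercept)
          err[li] <- err[li] + sum(e^2)
        }
      }
      best <- which.min(err)
      if (best == 1L || best == length(grid))
        warning("ridge penalty selected at grid edge (2^",
                log2(grid[best]), "); consider widening the grid")
      lam[f, k] <- grid[best]
      rp <- ridge_path(X[tr, , drop = FALSE], Y[tr, k])
      fit <- rp(grid[best])
      pred[te, k] <- X[te, , drop = FALSE] %*% fit$beta + fit$intercept
    }
  }
  nse_pred <- vapply(seq_len(ncol(Y)), function(k)
    nse(pred[, k], Y[, k]), 0)
  ev <- sign(1 - nse_pred) * (1 - nse_pred)^2
  structure(list(predicted = pred, target = Y, nse_pred = nse_pred,
                 explained_variance = ev, lambda = lam,
                 pairs = pairs, folds = folds, seed = seed),
            class = "prediction_result")
}

#' Bootstrap confidence intervals for prediction explained variance
#'
#' Resamples natural/synthetic pairs with replacement (1000 times by
#' default) and recomputes the NSE and sign-preserving explained variance
#' of the out-of-fold predictions on each resample. Squaring never flips
#' negative (1 - NSE) values positive, so anti-predictions keep their sign
#' and the bootstrap distribution is unbiased around zero for unpredictable
#' targets.
#'
#' @param result a `prediction_result`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param probs CI quantiles.
#' @return list with `ev` (n_boot x Kt matrix of resampled explained
#'   variances) and `ci` (quantiles per component).
#' @export
bootstrap_prediction <- function(result, n_boot = 1000, seed = 1,
                                 probs = c(0.025, 0.975)) {
  stopifnot(inherits(result, "prediction_result"))
  up <- unique(result$pairs)
  idx_of_pair <- lapply(up, function(p) which(result$pairs == p))
  K <- ncol(result$target)
  ev <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      sel <- unlist(idx_of_pair[sample.int(length(up), replace = TRUE)])
      vapply(seq_len(K), function(k) {
        ns <- nse(result$predicted[sel, k], result$target[sel, k])
        sign(1 - ns) * (1 - ns)^2
      }, 0)
    }, numeric(K)))
  })
  list(ev = ev, ci = apply(ev, 2, stats::quantile, probs = probs))
}

#' Explained-variance decomposition for synthetic sounds and
#' natural-minus-synthetic differences
#'
#' For each target component, measures prediction accuracy separately for
#' (a) responses to synthetic sounds and (b) the difference between
#' responses to natural and matched synthetic sounds, using two independent
#' measurements of predictions and targets for noise correction. The NSE is
#' noise-corrected only when the target's own test-retest NSE is below the
#' reliability gate (0.4); the total variance of each target component is
#' noise-corrected as `(var(r1 + r2) - var(r1 - r2)) / 4` and multiplied by
#' the explained-variance fraction.
#'
#' @param pred1,pred2 sounds x K predicted profiles from two independent
#'   measurements.
#' @param target1,target2 sounds x K target profiles from two independent
#'   measurements.
#' @param sound_table data.frame with `natural` flag and `pair` ids, rows
#'   matching the sound axis.
#' @param gate test-retest NSE gate for correction (default 0.4).
#' @return data.frame per component x quantity (`synthetic` /
#'   `difference`): NSE, corrected flag, explained-variance fraction, total
#'   variance, explained variance.
#' @export
explained_variance_decomposition <- function(pred1, pred2, target1, target2,
                                             sound_table, gate = 0.4) {
  stopifnot(all(dim(pred1) == dim(target1)))
  K <- ncol(target1)
  syn <- which(!sound_table$natural)
  nat <- match(sound_table$pair[syn], sound_table$pair[sound_table$natural])
  nat <- which(sound_table$natural)[nat]
  rows <- list()
  for (k in seq_len(K)) {
    for (what in c("synthetic", "difference")) {
      if (what == "synthetic") {
        x1 <- pred1[syn, k]; x2 <- pred2[syn, k]
        y1 <- target1[syn, k]; y2 <- target2[syn, k]
      } else {
        x1 <- pred1[nat, k] - pred1[syn, k]
        x2 <- pred2[nat, k] - pred2[syn, k]
        y1 <- target1[nat, k] - target1[syn, k]
        y2 <- target2[nat, k] - target2[syn, k]
      }
      trt <- nse(y1, y2)
      corrected <- is.finite(trt) && trt < gate
      ns <- if (corrected) noise_corrected_nse(x1, x2, y1, y2)
            else nse((x1 + x2) / 2, (y1 + y2) / 2)
      evf <- sign(1 - ns) * (1 - ns)^2
      tv <- noise_corrected_variance(y1, y2)
      rows[[length(rows) + 1]] <- data.frame(
        component = k, quantity = what, nse = ns, corrected = corrected,
        test_retest_nse = trt, ev_fraction = evf, total_variance = tv,
        explained_variance = evf * tv)
    }
  }
  do.call(rbind, rows)
}

#' Per-category component response profile and natural-vs-synthetic contrast
#'
#' @param profiles sounds x K matrix (or `component_set`).
#' @param sound_table data.frame with `category`, `natural`, `pair`.
#' @return list with `category_mean` (categories x K) and `contrast`
#'   (categories x K mean natural-minus-synthetic difference).
#' @export
component_category_profile <- function(profiles, sound_table) {
  P <- if (inherits(profiles, "component_set")) profiles$profiles
       else as.matrix(profiles)
  stopifnot(nrow(P) == nrow(sound_table))
  cats <- sort(unique(sound_table$category))
  cmean <- do.call(rbind, lapply(cats, function(cc)
    colMeans(P[sound_table$category == cc, , drop = FALSE])))
  syn <- which(!sound_table$natural)
  nat <- which(sound_table$natural)[
    match(sound_table$pair[syn], sound_table$pair[sound_table$natural])]
  diffs <- P[nat, , drop = FALSE] - P[syn, , drop = FALSE]
  dcat <- sound_table$category[nat]
  contrast <- do.call(rbind, lapply(cats, function(cc)
    colMeans(diffs[dcat == cc, , drop = FALSE])))
  rownames(cmean) <- rownames(contrast) <- cats
  list(category_mean = cmean, contrast = contrast)
}
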