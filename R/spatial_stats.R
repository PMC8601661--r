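## Map-level analyses: surface projection, annular distance-to-PAC
## profiles and slopes, cross-species slope sign tests, bootstrap model
## comparison, category-wise NSE with a shared normalization, normalized
## difference maps, and the video motion index.

#' Surface projection of a volume map
#'
#' Averages the variable of interest within each vertical column of masked
#' voxels (voxels sharing in-plane coordinates), i.e. perpendicular to the
#' cortical surface. Columns with no masked voxels yield `NA`.
#'
#' @param values per-voxel numeric vector.
#' @param geometry a `voxel_geometry` (or list with `coords`,
#'   `cortex_mask`); columns are defined by the (x, y) coordinates, depth
#'   is the third axis.
#' @param digits rounding applied to in-plane coordinates when grouping
#'   voxels into columns.
#' @return data.frame with `x`, `y`, `value` (column means) and `n_voxels`.
#' @export
surface_projection <- function(values, geometry, digits = 6) {
  stopifnot(length(values) == nrow(geometry$coords))
  mask <- geometry$cortex_mask
  key <- paste(round(geometry$coords[, 1], digits),
               round(geometry$coords[, 2], digits))
  keep <- mask & is.finite(values)
  agg <- tapply(values[keep], key[keep], mean)
  nv <- tapply(values[keep], key[keep], length)
  xy <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]),
                    value = as.numeric(agg), n_voxels = as.integer(nv))
  ## report empty columns (present in the mask but all-NA values)
  all_cols <- unique(key[mask])
  missing <- setdiff(all_cols, names(agg))
  if (length(missing) > 0) {
    xy2 <- do.call(rbind, strsplit(missing, " "))
    out <- rbind(out, data.frame(x = as.numeric(xy2[, 1]),
                                 y = as.numeric(xy2[, 2]),
                                 value = NA_real_, n_voxels = 0L))
  }
  out[order(out$x, out$y), ]
}

#' Annular profile of NSE versus distance to primary auditory cortex
#'
#' Bins cortical voxels by their distance to the tonotopically defined PAC
#' center and reports the median (corrected) NSE per bin, along with the
#' least-squares slope of the median-versus-distance relationship over the
#' populated bins (absolute distances, unweighted).
#'
#' @param values per-voxel NSE values, or an `nse_result` (its
#'   `corrected_nse` gated by `valid_mask` is used).
#' @param geometry a `voxel_geometry` with `distance_to_pac`.
#' @param bin_size bin width in mm (ferret default 0.5; human 5).
#' @return object of class `annular_profile`: `bin_centers`, `median_nse`,
#'   `n_voxels`, `slope` (NSE per mm), `intercept`, `bin_size`.
#' @export
annular_profile <- function(values, geometry, bin_size = 0.5) {
  if (inherits(values, "nse_result")) {
    v <- values$corrected_nse
    v[!values$valid_mask] <- NA_real_
  } else v <- values
  stopifnot(length(v) == nrow(geometry$coords), bin_size > 0)
  d <- geometry$distance_to_pac
  keep <- geometry$cortex_mask & is.finite(v) & is.finite(d)
  bin <- floor(d[keep] / bin_size)
  med <- tapply(v[keep], bin, stats::median)
  nv <- tapply(v[keep], bin, length)
  centers <- (as.numeric(names(med)) + 0.5) * bin_size
  o <- order(centers)
  centers <- centers[o]; med <- as.numeric(med)[o]
  slope <- intercept <- NA_real_
  if (length(centers) >= 2) {
    fit <- stats::lm.fit(cbind(1, centers), med)
    intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  } else warning("fewer than 2 populated bins; slope undefined")
  structure(list(bin_centers = centers, median_nse = med,
                 n_voxels = as.integer(nv)[o],
                 slope = unname(slope), intercept = unname(intercept),
                 bin_size = bin_size),
            class = "annular_profile")
}

#' Sign test of each ferret slope against the human slope distribution
#'
#' Exact two-sided binomial sign test: under the null that a ferret's slope
#' is drawn from the human distribution, the number of human slopes below
#' it is Binomial(n, 1/2). Ties are dropped (and logged).
#'
#' @param ferret_slopes numeric vector (one slope per ferret).
#' @param human_slopes numeric vector (>= 2 human subjects).
#' @return data.frame per ferret: slope, number of human slopes below, n
#'   used, p-value.
#' @export
compare_slopes <- function(ferret_slopes, human_slopes) {
  stopifnot(length(human_slopes) >= 1)
  if (length(human_slopes) < 2)
    warning("only one comparator slope: sign test is uninformative (p = 1)")
  out <- lapply(seq_along(ferret_slopes), function(i) {
    fs <- ferret_slopes[i]
    ties <- sum(human_slopes == fs)
    if (ties > 0) message(ties, " tied slope(s) dropped from the sign test")
    hs <- human_slopes[human_slopes != fs]
    k <- sum(hs < fs)
    p <- if (length(hs) == 0) 1 else
      stats::binom.test(k, length(hs), 0.5)$p.value
    data.frame(ferret = i, slope = fs, n_below = k, n_used = length(hs),
               p_value = p)
  })
  do.call(rbind, out)
}

## Wilcoxon tests: exact for small tie-free samples, normal approximation
## with continuity correction otherwise.
wilcox_p <- function(a, b, paired = FALSE) {
  exact <- (length(a) + length(b)) <= 25 && !any(duplicated(c(a, b))) &&
    (!paired || !any(a == b))
  stats::wilcox.test(a, b, paired = paired, exact = exact,
                     correct = TRUE)$p.value
}

## Vectorized per-voxel corrected-NSE terms over a sound subset.
corrected_terms <- function(X1, X2, Y1, Y2, cols = seq_len(ncol(X1))) {
  x1 <- X1[, cols, drop = FALSE]; x2 <- X2[, cols, drop = FALSE]
  y1 <- Y1[, cols, drop = FALSE]; y2 <- Y2[, cols, drop = FALSE]
  list(
    px = 0.5 * rowMeans(x1^2) + 0.5 * rowMeans(x2^2) -
      0.5 * rowMeans((x1 - x2)^2),
    py = 0.5 * rowMeans(y1^2) + 0.5 * rowMeans(y2^2) -
      0.5 * rowMeans((y1 - y2)^2),
    mx = rowMeans((x1 + x2) / 2), my = rowMeans((y1 + y2) / 2),
    cxy = 0.25 * (rowMeans(x1 * y1) + rowMeans(x1 * y2) +
                  rowMeans(x2 * y1) + rowMeans(x2 * y2)))
}

#' Bootstrap comparison of models by median NSE
#'
#' For each bootstrap draw, resamples the sound pairs with replacement,
#' recomputes each model's per-voxel corrected NSE from its split response
#' matrices, takes the median across voxels, and compares models by the
#' fraction of draws on which their order flips (times 2 for a two-sided
#' p-value, floored at 2 / n_boot).
#'
#' @param models named list; each element a list with voxels x sounds split
#'   matrices `X1`, `X2` (natural) and `Y1`, `Y2` (that model's synthetic).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @return list with `median_nse` (observed per model), `boot` (n_boot x
#'   models draws), `p` (pairwise two-sided p-values).
#' @export
bootstrap_model_comparison <- function(models, n_boot = 1000, seed = 1) {
  stopifnot(length(models) >= 2, !is.null(names(models)))
  n_sounds <- ncol(models[[1]]$X1)
  med_nse <- function(m, cols) {
    tm <- corrected_terms(m$X1, m$X2, m$Y1, m$Y2, cols)
    stats::median((tm$px + tm$py - 2 * tm$cxy) /
                  (tm$px + tm$py - 2 * tm$mx * tm$my), na.rm = TRUE)
  }
  obs <- vapply(models, med_nse, 0, cols = seq_len(n_sounds))
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      cols <- sample.int(n_sounds, replace = TRUE)
      vapply(models, med_nse, 0, cols = cols)
    }, numeric(length(models))))
  })
  nm <- names(models)
  p <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    d <- boot[, i] - boot[, j]
    p[i, j] <- p[j, i] <-
      min(1, max(2 * min(mean(d >= 0), mean(d <= 0)), 2 / n_boot))
  }
  list(median_nse = obs, boot = boot, p = p)
}

#' Per-category noise-corrected NSE with a shared normalization
#'
#' The NSE numerator (corrected residual power between natural and
#' synthetic responses) is restricted to each category's sound pairs, while
#' the denominator is computed from all sounds, so the normalization is
#' identical across categories and genuine category differences are not
#' normalized away. Also returns a per-sound NSE (per-pair numerator over
#' the shared denominator, median across voxels) and Wilcoxon rank-sum
#' tests between categories over those per-sound values.
#'
#' @param X1,X2 voxels x pairs natural-response splits (columns ordered by
#'   pair).
#' @param Y1,Y2 voxels x pairs matched-synthetic splits (same pair order).
#' @param categories per-pair category labels.
#' @return list with `category_nse` (median across voxels per category),
#'   `per_sound_nse`, `tests` (pairwise rank-sum p-values).
#' @export
category_nse <- function(X1, X2, Y1, Y2, categories) {
  stopifnot(length(categories) == ncol(X1))
  cats <- sort(unique(categories))
  small <- cats[table(factor(categories, cats)) < 2]
  if (length(small) > 0) {
    message("excluding categories with < 2 sounds: ",
            paste(small, collapse = ", "))
    cats <- setdiff(cats, small)
  }
  all_terms <- corrected_terms(X1, X2, Y1, Y2)
  den <- all_terms$px + all_terms$py - 2 * all_terms$mx * all_terms$my
  num_for <- function(cols) {
    tm <- corrected_terms(X1, X2, Y1, Y2, cols)
    tm$px + tm$py - 2 * tm$cxy
  }
  cat_nse <- vapply(cats, function(cc)
    stats::median((num_for(which(categories == cc)) / den)[den > 0],
                  na.rm = TRUE), 0)
  per_sound <- vapply(seq_len(ncol(X1)), function(s)
    stats::median((num_for(s) / den)[den > 0], na.rm = TRUE), 0)
  tests <- matrix(NA_real_, length(cats), length(cats),
                  dimnames = list(cats, cats))
  for (i in seq_along(cats)) for (j in seq_along(cats)) if (i < j) {
    tests[i, j] <- tests[j, i] <- wilcox_p(per_sound[categories == cats[i]],
                                           per_sound[categories == cats[j]])
  }
  list(category_nse = cat_nse, per_sound_nse = per_sound,
       categories = categories, tests = tests)
}

#' Normalized natural-minus-synthetic difference map per category
#'
#' Mean difference between natural and matched synthetic responses over
#' each category's pairs, divided by the standard deviation of the voxel's
#' response across all sounds (making the scale comparable across voxels
#' and species). Voxels with zero s.d. yield `NA`.
#'
#' @param natural,synthetic voxels x pairs response matrices (matched
#'   column order).
#' @param categories per-pair category labels.
#' @return voxels x categories matrix of normalized differences.
#' @export
difference_map <- function(natural, synthetic, categories) {
  stopifnot(all(dim(natural) == dim(synthetic)),
            length(categories) == ncol(natural))
  allresp <- cbind(natural, synthetic)
  sdv <- apply(allresp, 1, stats::sd)
  sdv[sdv == 0] <- NA_real_
  cats <- sort(unique(categories))
  out <- sapply(cats, function(cc)
    rowMeans(natural[, categories == cc, drop = FALSE] -
             synthetic[, categories == cc, drop = FALSE]) / sdv)
  colnames(out) <- cats
  out
}

#' Video motion index per sound, with category tests
#'
#' Frame-to-frame motion is the sum over ROI pixels of absolute deviations
#' between adjacent frames. Evoked movement per trial is computed like the
#' imaging signals: the mean baseline-period motion of the trial is
#' removed, then divided by the session's mean baseline motion. Per-sound
#' indices are normalized within session by the standard deviation across
#' sounds (absorbing camera-angle/gain differences) and averaged across
#' sessions. Wilcoxon signed-rank tests compare natural vs matched
#' synthetic sounds within category; rank-sum tests compare categories.
#'
#' @param frames n_frames x n_pixels matrix of video frames, trials
#'   contiguous (`frames_per_trial` rows each) in `trial_table` order.
#' @param trial_table data.frame with `sound`, `session` per trial.
#' @param sound_table data.frame with `category`, `natural`, `pair`.
#' @param frames_per_trial frames per trial.
#' @param baseline_frames index range (within trial) of baseline frames.
#' @param stim_frames index range (within trial) of stimulus frames.
#' @param roi optional logical/integer pixel subset.
#' @return list with `motion_table` (per-sound index, category, natural
#'   flag), `natsynth_tests` (signed-rank per category), `category_tests`
#'   (rank-sum between categories, natural sounds only).
#' @export
motion_index <- function(frames, trial_table, sound_table, frames_per_trial,
                         baseline_frames, stim_frames, roi = NULL) {
  frames <- as.matrix(frames)
  if (!is.null(roi)) frames <- frames[, roi, drop = FALSE]
  n_trials <- nrow(trial_table)
  stopifnot(nrow(frames) == n_trials * frames_per_trial)
  motion <- c(0, rowSums(abs(frames[-1, , drop = FALSE] -
                             frames[-nrow(frames), , drop = FALSE])))
  per_trial <- matrix(motion, nrow = frames_per_trial)   # frames x trials
  per_trial[1, ] <- per_trial[2, ]   # first frame has no predecessor
  base <- colMeans(per_trial[baseline_frames, , drop = FALSE])
  stim <- colMeans(per_trial[stim_frames, , drop = FALSE])
  evoked <- numeric(n_trials)
  for (ss in unique(trial_table$session)) {
    idx <- trial_table$session == ss
    sb <- mean(base[idx])
    if (sb <= 0) sb <- 1
    evoked[idx] <- (stim[idx] - base[idx]) / sb
  }
  ## per sound within session, then session-normalize and average
  sessions <- unique(trial_table$session)
  per_sound <- sapply(sessions, function(ss) {
    idx <- trial_table$session == ss
    m <- tapply(evoked[idx], trial_table$sound[idx], mean)
    v <- rep(NA_real_, nrow(sound_table))
    v[as.integer(names(m))] <- m
    sdv <- stats::sd(v, na.rm = TRUE)
    if (is.finite(sdv) && sdv > 0) v / sdv else v
  })
  per_sound <- rowMeans(as.matrix(per_sound), na.rm = TRUE)
  tab <- data.frame(sound = seq_len(nrow(sound_table)),
                    index = per_sound,
                    category = sound_table$category,
                    natural = sound_table$natural,
                    pair = sound_table$pair)
  cats <- sort(unique(tab$category))
  natsynth <- lapply(cats, function(cc) {
    nat <- tab[tab$natural & tab$category == cc, ]
    syn <- tab[!tab$natural & tab$category == cc, ]
    syn <- syn[match(nat$pair, syn$pair), ]
    if (nrow(nat) < 2 || anyNA(syn$index) || anyNA(nat$index))
      return(data.frame(category = cc, p_value = NA_real_))
    data.frame(category = cc,
               p_value = wilcox_p(nat$index, syn$index, paired = TRUE))
  })
  cat_tests <- matrix(NA_real_, length(cats), length(cats),
                      dimnames = list(cats, cats))
  natonly <- tab[tab$natural & is.finite(tab$index), ]
  for (i in seq_along(cats)) for (j in seq_along(cats)) if (i < j) {
    a <- natonly$index[natonly$category == cats[i]]
    b <- natonly$index[natonly$category == cats[j]]
    if (length(a) >= 2 && length(b) >= 2)
      cat_tests[i, j] <- cat_tests[j, i] <- wilcox_p(a, b)
  }
  list(motion_table = tab,
       natsynth_tests = do.call(rbind, natsynth),
       category_tests = cat_tests)
}
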