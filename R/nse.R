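## Normalized squared error (NSE) statistics and noise-corrected variants.
##
## The NSE between two paired response vectors x and y is
##     NSE = mu([x - y]^2) / (mu(x^2) + mu(y^2) - 2 mu(x) mu(y))
## where mu() is the mean over elements. It is 0 for identical responses,
## 1 in expectation for independent responses, and reaches 2 for zero-mean
## perfectly anticorrelated responses. Expanding the numerator,
##     NSE = (mu(x^2) + mu(y^2) - 2 mu(x o y)) / (mu(x^2) + mu(y^2) - 2 mu(x) mu(y)),
## which shows the statistic is a function of powers, means and a
## cross-product. Means and cross-products are unbiased by zero-mean
## measurement noise; the powers are biased upward by the noise power, which
## can be estimated from the residual between two independent repetitions
## (the residual power equals twice the noise power in expectation). The
## noise-corrected NSE replaces the powers with their corrected estimates so
## that the expected value is 0 when the two conditions share one underlying
## signal, regardless of measurement SNR.

#' Normalized squared error between two response vectors
#'
#' Dissimilarity of two paired response vectors: 0 if identical, about 1 for
#' independent responses, up to 2 for zero-mean anticorrelated responses.
#' Sensitive to differences in mean and scale as well as pattern, unlike the
#' Pearson correlation.
#'
#' @param x,y numeric vectors of equal length (>= 2), e.g. the responses of a
#'   voxel across sounds under two conditions.
#' @return a single numeric value; `NA` (with a warning) if the denominator
#'   is zero, which happens only when both vectors are constant with equal
#'   means.
#' @examples
#' nse(c(1, 2, 3), c(1, 2, 3))   # 0
#' nse(c(1, 2, 3), c(1, 2, 4))   # 1/7
#' @export
nse <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  num <- mean((x - y)^2)
  den <- mean(x^2) + mean(y^2) - 2 * mean(x) * mean(y)
  if (!is.finite(den) || den == 0) {
    warning("NSE undefined: zero denominator (constant, equal-mean vectors)")
    return(NA_real_)
  }
  num / den
}

#' Row-wise NSE between two response matrices
#'
#' @param X,Y numeric matrices (voxels x sounds) with identical dimensions.
#' @return numeric vector of per-row NSE values.
#' @export
nse_rows <- function(X, Y) {
  stopifnot(all(dim(X) == dim(Y)))
  num <- rowMeans((X - Y)^2)
  den <- rowMeans(X^2) + rowMeans(Y^2) - 2 * rowMeans(X) * rowMeans(Y)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Noise-corrected response power
#'
#' Unbiased estimate of the power `mu(s^2)` of the shared signal underlying
#' two independent measurements `x1`, `x2` of the same condition: half the
#' two measured powers minus half the residual power. Negative values can
#' occur by sampling noise and are returned as-is.
#'
#' @param x1,x2 numeric vectors: two independent measurements (e.g. odd and
#'   even stimulus repetitions).
#' @return single numeric value.
#' @export
noise_corrected_power <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  0.5 * mean(x1^2) + 0.5 * mean(x2^2) - 0.5 * mean((x1 - x2)^2)
}

#' Noise-corrected NSE from split measurements of two conditions
#'
#' Evaluates the NSE with the noise-biased power terms replaced by their
#' corrected estimates, so the expected value is 0 when both conditions share
#' one underlying signal. The cross-product term is averaged over the four
#' split pairings (x_i, y_j), each of which is unbiased. When only one
#' measurement of `y` is available (`y2 = NULL`), the noise power of `x` is
#' used to correct the power of `y` as well (single-repeat paradigm support).
#'
#' @param x1,x2 two independent measurements of condition x.
#' @param y1 measurement of condition y.
#' @param y2 optional second measurement of condition y.
#' @return single numeric value (may be negative or exceed raw bounds by
#'   sampling noise; reported uncorrected for sign).
#' @export
noise_corrected_nse <- function(x1, x2, y1, y2 = NULL) {
  stopifnot(length(x1) == length(x2), length(x1) == length(y1))
  px <- noise_corrected_power(x1, x2)
  mx <- mean((x1 + x2) / 2)
  if (is.null(y2)) {
    py <- mean(y1^2) - 0.5 * mean((x1 - x2)^2)
    my <- mean(y1)
    cxy <- 0.5 * (mean(x1 * y1) + mean(x2 * y1))
  } else {
    stopifnot(length(y1) == length(y2))
    py <- noise_corrected_power(y1, y2)
    my <- mean((y1 + y2) / 2)
    cxy <- 0.25 * (mean(x1 * y1) + mean(x1 * y2) +
                   mean(x2 * y1) + mean(x2 * y2))
  }
  num <- px + py - 2 * cxy
  den <- px + py - 2 * mx * my
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}

#' Per-voxel noise-corrected NSE map with reliability gating
#'
#' Applies [noise_corrected_nse()] row-wise to split response matrices and
#' gates voxels on their test-retest NSE (the NSE between the two splits of
#' the x condition, and of the y condition when available): voxels whose
#' test-retest NSE is at or above `gate` (default 0.4) are reported but
#' excluded from `valid_mask`, as are voxels with a non-positive corrected
#' denominator.
#'
#' @param X1,X2 voxels x sounds matrices: two measurement splits of
#'   condition x (e.g. natural sounds, odd/even repetitions).
#' @param Y1 voxels x sounds matrix for condition y (e.g. synthetic sounds).
#' @param Y2 optional second split of condition y.
#' @param gate test-retest NSE threshold for `valid_mask`.
#' @return an object of class `nse_result`: list with `raw_nse`,
#'   `corrected_nse`, `test_retest_nse` and logical `valid_mask`, all per
#'   voxel.
#' @export
nse_map <- function(X1, X2, Y1, Y2 = NULL, gate = 0.4) {
  stopifnot(all(dim(X1) == dim(X2)), all(dim(X1) == dim(Y1)))
  xa <- (X1 + X2) / 2
  ya <- if (is.null(Y2)) Y1 else (Y1 + Y2) / 2
  raw <- nse_rows(xa, ya)
  trt <- nse_rows(X1, X2)
  if (is.null(Y2)) {
    px <- 0.5 * rowMeans(X1^2) + 0.5 * rowMeans(X2^2) -
      0.5 * rowMeans((X1 - X2)^2)
    py <- rowMeans(Y1^2) - 0.5 * rowMeans((X1 - X2)^2)
    mx <- rowMeans(xa); my <- rowMeans(Y1)
    cxy <- 0.5 * (rowMeans(X1 * Y1) + rowMeans(X2 * Y1))
  } else {
    tm <- corrected_terms(X1, X2, Y1, Y2)
    px <- tm$px; py <- tm$py; mx <- tm$mx; my <- tm$my; cxy <- tm$cxy
    trt <- pmax(trt, nse_rows(Y1, Y2))
  }
  den <- px + py - 2 * mx * my
  den_ok <- is.finite(den) & den > 0
  corrected <- ifelse(is.finite(den) & den != 0,
                      (px + py - 2 * cxy) / den, NA_real_)
  structure(list(
    raw_nse = raw,
    corrected_nse = corrected,
    test_retest_nse = trt,
    valid_mask = is.finite(trt) & trt < gate & den_ok & is.finite(corrected),
    gate = gate
  ), class = "nse_result")
}

#' Noise-corrected variance of a shared signal
#'
#' Given two independent measurements `r1 = s + n1`, `r2 = s + n2` of the
#' same signal `s`, `(var(r1 + r2) - var(r1 - r2)) / 4` is an unbiased
#' estimate of `var(s)`: the noise variances cancel between the sum and the
#' difference.
#'
#' @param r1,r2 numeric vectors: two independent measurements.
#' @return single numeric value (negative values possible by sampling noise).
#' @export
noise_corrected_variance <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 2)
  (stats::var(r1 + r2) - stats::var(r1 - r2)) / 4
}

#' Between-split spatial correlation as a function of voxel distance
#'
#' For every voxel pair (i, j), correlates the split-A response of voxel i
#' with the split-B response of voxel j across sounds (symmetrized over the
#' two split assignments), then averages within distance bins. The 0 mm bin
#' (i = j) measures test-retest reliability; the decay with distance measures
#' spatial precision.
#'
#' @param split_a,split_b voxels x sounds response matrices from independent
#'   repetition splits (odd vs even).
#' @param coords voxels x d matrix of positions in mm (d = 2 or 3).
#' @param bin_size bin width in mm (0.5 for ferret fUS, 3 for human fMRI).
#' @return object of class `spatial_profile`: list with `distance` (bin
#'   centers, mm), `correlation` (mean per bin), `n_pairs`, `bin_size`.
#' @export
spatial_correlation_profile <- function(split_a, split_b, coords,
                                        bin_size = 0.5) {
  stopifnot(all(dim(split_a) == dim(split_b)),
            nrow(coords) == nrow(split_a), bin_size > 0)
  Za <- standardize_cols(t(split_a))   # sounds x voxels, standardized
  Zb <- standardize_cols(t(split_b))
  ns <- nrow(Za)
  C <- crossprod(Za, Zb) / (ns - 1)    # voxels x voxels cross-split corr
  C <- (C + t(C)) / 2                  # symmetrize over split assignment
  D <- as.matrix(stats::dist(coords))
  idx <- upper.tri(D, diag = TRUE)
  d <- D[idx]; r <- C[idx]
  bin <- floor(d / bin_size + 0.5)     # bin centered on multiples of bin_size
  keep <- is.finite(r)
  agg <- tapply(r[keep], bin[keep], mean)
  npair <- tapply(r[keep], bin[keep], length)
  centers <- as.numeric(names(agg)) * bin_size
  o <- order(centers)
  structure(list(distance = centers[o],
                 correlation = as.numeric(agg)[o],
                 n_pairs = as.integer(npair)[o],
                 bin_size = bin_size),
            class = "spatial_profile")
}

#' Distance at which the spatial correlation decays by 75 percent
#'
#' Subtracts the minimum correlation across all distances (removing any
#' globally shared baseline), then finds by linear interpolation the first
#' distance at which the profile crosses 25 percent of its zero-distance
#' value.
#'
#' @param profile a `spatial_profile` from [spatial_correlation_profile()],
#'   or a list with `distance` and `correlation` vectors.
#' @return distance in mm; `NA` (with a warning) if the profile never decays
#'   below the 25 percent level.
#' @export
tau75 <- function(profile) {
  d <- profile$distance
  f <- profile$correlation
  stopifnot(length(d) == length(f), length(d) >= 2)
  o <- order(d)
  d <- d[o]; f <- f[o]
  f <- f - min(f)
  target <- 0.25 * f[1]
  below <- which(f <= target)
  below <- below[below > 1]
  if (f[1] <= 0 || length(below) == 0) {
    warning("spatial profile never decays below 25% of its peak; tau75 undefined")
    return(NA_real_)
  }
  j <- below[1]
  i <- j - 1
  if (f[i] == f[j]) return(d[j])
  d[i] + (d[j] - d[i]) * (f[i] - target) / (f[i] - f[j])
}
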