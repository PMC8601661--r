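test_that("nse matches hand-computed and boundary values", {
  expect_equal(nse(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(1, -1, 2, -2)           # zero mean
  expect_equal(nse(x, -x), 2)
  expect_equal(nse(c(1, 2, 3), c(1, 2, 4)), 1 / 7)
  # undefined denominator: constant equal-mean vectors
  expect_warning(out <- nse(c(2, 2), c(2, 2)), "undefined")
  expect_true(is.na(out))
})

test_that("nse is symmetric and scale-invariant", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(nse(x, y), nse(y, x))
    k <- runif(1, 0.1, 10)
    expect_equal(nse(k * x, k * y), nse(x, y), tolerance = 1e-12)
  }
})

test_that("1 - nse equals Pearson correlation for standardized vectors", {
  set.seed(2)
  for (i in 1:20) {
    x <- scale(rnorm(50)); y <- scale(rnorm(50))
    # scale() gives exact mean 0, sd 1
    expect_equal(1 - nse(as.numeric(x), as.numeric(y)),
                 cor(x, y)[1, 1], tolerance = 1e-10)
  }
})

test_that("nse_rows agrees with nse applied per row", {
  set.seed(3)
  X <- matrix(rnorm(60), 5); Y <- matrix(rnorm(60), 5)
  expect_equal(nse_rows(X, Y),
               sapply(1:5, function(v) nse(X[v, ], Y[v, ])))
})

test_that("noise-corrected power matches hand computation and is unbiased", {
  s <- c(3, -1, 2)
  expect_equal(noise_corrected_power(s, s), mean(s^2))
  expect_equal(noise_corrected_power(c(1.5, -0.5), c(0.5, -1.5)), 0.75)
  # Monte-Carlo unbiasedness: mean over many draws approaches mu(s^2)
  set.seed(4)
  s <- rnorm(50)
  est <- replicate(2000, {
    noise_corrected_power(s + rnorm(50, sd = 0.8), s + rnorm(50, sd = 0.8))
  })
  expect_equal(mean(est), mean(s^2), tolerance = 0.01 * mean(s^2) + 0.01)
})

test_that("noise-corrected NSE is 0 for shared signal, 1 for independent", {
  set.seed(5)
  expect_equal(noise_corrected_nse(c(1, 2, 3), c(1, 2, 3),
                                   c(1, 2, 3), c(1, 2, 3)), 0)
  # noisy splits of one signal: mean near 0
  vals <- replicate(500, {
    s <- rnorm(80)
    noise_corrected_nse(s + rnorm(80, sd = 0.6), s + rnorm(80, sd = 0.6),
                        s + rnorm(80, sd = 0.6), s + rnorm(80, sd = 0.6))
  })
  expect_lt(abs(mean(vals)), 0.03)
  # independent signals: mean near 1
  vals <- replicate(500, {
    sx <- rnorm(100); sy <- rnorm(100)
    noise_corrected_nse(sx + rnorm(100, sd = .3), sx + rnorm(100, sd = .3),
                        sy + rnorm(100, sd = .3), sy + rnorm(100, sd = .3))
  })
  expect_lt(abs(mean(vals) - 1), 0.07)
})

test_that("single-measurement correction borrows x's noise power", {
  set.seed(6)
  vals <- replicate(1000, {
    s <- rnorm(80)
    noise_corrected_nse(s + rnorm(80, sd = 0.5), s + rnorm(80, sd = 0.5),
                        s + rnorm(80, sd = 0.5))
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("noise-corrected variance recovers planted signal variance", {
  s <- c(1, 5, -2, 0.5)
  expect_equal(noise_corrected_variance(s, s), var(s))
  set.seed(7)
  # independent pure noise: expectation 0
  est <- replicate(2000, noise_corrected_variance(rnorm(30), rnorm(30)))
  expect_lt(abs(mean(est)), 0.02)
  # planted variance 4 with unit noise
  n <- 1e5
  s <- rnorm(n, sd = 2)
  est <- noise_corrected_variance(s + rnorm(n), s + rnorm(n))
  expect_equal(est, 4, tolerance = 0.05)
})

test_that("nse_map gates voxels on test-retest reliability", {
  set.seed(8)
  n_s <- 40
  S <- matrix(rnorm(20 * n_s), 20)
  mk <- function(sd) S + matrix(rnorm(20 * n_s, sd = sd), 20)
  # half the voxels reliable, half hopeless
  noise_sd <- rep(c(0.3, 5), each = 10)
  X1 <- S + noise_sd * matrix(rnorm(20 * n_s), 20)
  X2 <- S + noise_sd * matrix(rnorm(20 * n_s), 20)
  Y1 <- S + noise_sd * matrix(rnorm(20 * n_s), 20)
  Y2 <- S + noise_sd * matrix(rnorm(20 * n_s), 20)
  res <- nse_map(X1, X2, Y1, Y2)
  expect_s3_class(res, "nse_result")
  expect_true(all(res$test_retest_nse[1:10] < 0.4))
  expect_true(all(!res$valid_mask[11:20]))
  expect_true(all(res$raw_nse >= 0))
  # corrected values of reliable voxels near 0 (same signal both conditions)
  expect_lt(abs(median(res$corrected_nse[1:10])), 0.1)
})

test_that("spatial correlation profile recovers planted smoothing scale", {
  set.seed(9)
  n_vox <- 80; n_snd <- 400; lambda <- 2
  coords <- cbind(seq_len(n_vox) * 0.5, 0, 0)   # 1D line, 0.5 mm spacing
  G <- exp(-outer(coords[, 1], coords[, 1], "-")^2 / (2 * lambda^2))
  R <- G %*% matrix(rnorm(n_vox * n_snd), n_vox)
  prof <- spatial_correlation_profile(R, R, coords, bin_size = 0.5)
  expect_equal(prof$correlation[1], 1, tolerance = 1e-6)  # 0 mm, identical splits
  # analytic decay: corr(d) = exp(-d^2 / (4 lambda^2)); fit scale within 10%
  sel <- prof$distance > 0 & prof$distance < 2 * lambda &
    prof$correlation > 0.05
  fit <- lm(log(prof$correlation[sel]) ~ 0 + I(prof$distance[sel]^2))
  lambda_hat <- sqrt(-1 / (4 * coef(fit)[[1]]))
  expect_equal(lambda_hat, lambda, tolerance = 0.1)
})

test_that("spatially independent voxels give a flat profile beyond 0 mm", {
  set.seed(10)
  n_vox <- 60; n_snd <- 200
  S <- matrix(rnorm(n_vox * n_snd), n_vox)
  A <- S + matrix(rnorm(n_vox * n_snd, sd = 0.5), n_vox)
  B <- S + matrix(rnorm(n_vox * n_snd, sd = 0.5), n_vox)
  coords <- cbind(seq_len(n_vox) * 2, 0, 0)   # spaced: 0 mm bin is diagonal only
  prof <- spatial_correlation_profile(A, B, coords, bin_size = 1)
  expect_gt(prof$correlation[1], 0.7)   # test-retest reliability at 0 mm
  expect_lt(max(abs(prof$correlation[-1])), 0.1)
})

test_that("tau75 solves the 75% decay point", {
  lambda <- 1.5
  d <- seq(0, 15, by = 0.05)
  prof <- list(distance = d, correlation = exp(-d / lambda))
  expect_equal(tau75(prof), lambda * log(4), tolerance = 0.01)
  # offset invariance (min subtraction)
  prof2 <- list(distance = d, correlation = exp(-d / lambda) + 0.3)
  expect_equal(tau75(prof2), tau75(prof), tolerance = 0.02)
  # constant profile: undefined
  expect_warning(out <- tau75(list(distance = d, correlation = rep(1, length(d)))),
                 "undefined")
  expect_true(is.na(out))
})
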