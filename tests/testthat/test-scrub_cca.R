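test_that("trial residuals remove the across-repetition mean", {
  ds <- percent_signal_change(small_dataset(seed = 21, n_reps = 2))
  res <- trial_residuals(ds)
  # two repetitions a, b of one sound -> residuals +/- (a - b) / 2
  tab <- ds$trial_table
  tr <- which(tab$sound == 1)
  a <- ds$data[5, tr[1], ]; b <- ds$data[5, tr[2], ]
  n_t <- dim(ds$data)[3]
  pos1 <- (which(res$trials == tr[1]) - 1) * n_t + seq_len(n_t)
  expect_equal(res$residuals[pos1, 5], (a - b) / 2)
  # residuals have zero mean per sound by construction
  nl <- percent_signal_change(
    small_dataset(seed = 22, n_reps = 2, snr = 0, motion_sd = 0))
  expect_lt(max(abs(trial_residuals(nl)$residuals)), 1e-12)
})

test_that("single-repetition sounds are excluded with a warning", {
  ds <- percent_signal_change(small_dataset(seed = 23, n_reps = 2))
  # drop the second repetition of sound 1
  drop <- which(ds$trial_table$sound == 1 & ds$trial_table$rep == 2)
  ds$data <- ds$data[, -drop, , drop = FALSE]
  ds$trial_table <- ds$trial_table[-drop, ]
  expect_warning(res <- trial_residuals(ds), "single-repetition")
  expect_false(any(ds$trial_table$sound[res$trials] == 1))
})

test_that("regularized CCA matches stats::cancor in the well-posed regime", {
  set.seed(24)
  n <- 400
  Z <- matrix(rnorm(n * 2), n)             # two shared latents
  X <- Z %*% matrix(rnorm(2 * 5), 2) + matrix(rnorm(n * 5, sd = 1), n)
  Y <- Z %*% matrix(rnorm(2 * 4), 2) + matrix(rnorm(n * 4, sd = 1), n)
  b <- fit_noise_basis(X, Y, k = 4, shrinkage = 1e-10)
  ref <- cancor(X, Y)
  expect_equal(b$cancor, ref$cor, tolerance = 1e-6)
})

test_that("fit_noise_basis finds planted shared motion", {
  gt <- make_ground_truth(n_pairs = 8, K = 3, n_slices = 2,
                          voxels_per_slice = 40, out_voxels_per_slice = 20,
                          motion_sd = 4, seed = 25)
  ds <- percent_signal_change(simulate_trials(gt, n_reps = 4, seed = 26))
  mask <- gt$geometry$cortex_mask
  in_res <- trial_residuals(ds, voxels = which(mask))
  out_res <- trial_residuals(ds, voxels = which(!mask))
  b <- fit_noise_basis(in_res$residuals, out_res$residuals, k = 8)
  expect_gt(b$cancor[1], 0.9)
  expect_true(all(diff(b$cancor) <= 1e-10))
  expect_equal(colSums(b$timecourses^2), rep(1, b$k), tolerance = 1e-8)
  # the full-data noise timecourses (what removal projects out) capture the
  # planted motion trace of each slice
  Mout <- fusnatsynth:::flatten_time(ds)[, which(!mask)]
  Zfull <- sweep(Mout, 2, b$out_center, "-") %*% b$weights_out
  caps <- sapply(1:2, function(s) {
    m <- as.vector(sapply(seq_len(ncol(ds$aux$motion_amp)), function(j)
      ds$aux$motion_amp[s, j] * ds$aux$motion_shape))
    summary(lm(m ~ Zfull))$r.squared
  })
  expect_gt(max(caps), 0.8)
  # without shared noise, canonical correlations stay near the permuted-
  # time-block chance level
  gt0 <- small_truth(seed = 27, motion_sd = 0, slice_noise_frac = 0)
  ds0 <- percent_signal_change(simulate_trials(gt0, n_reps = 4, seed = 28))
  mask0 <- gt0$geometry$cortex_mask
  in0 <- trial_residuals(ds0, voxels = which(mask0))$residuals
  out0 <- trial_residuals(ds0, voxels = which(!mask0))$residuals
  b0 <- fit_noise_basis(in0, out0, k = 8)
  null_cc <- fit_noise_basis(in0, out0[sample(nrow(out0)), ], k = 8)
  expect_lt(b0$cancor[1], null_cc$cancor[1] + 0.1)
})

test_that("component removal is a projection and k = 0 is the identity", {
  ds <- percent_signal_change(small_dataset(seed = 29, n_reps = 2))
  empty <- fit_noise_basis(matrix(rnorm(100), 50), matrix(rnorm(100), 50),
                           k = 0)
  expect_equal(remove_noise_components(ds, empty)$data, ds$data)
  out <- scrub_dataset(ds, k = 5)
  # projection never increases any voxel timecourse norm
  M0 <- fusnatsynth:::flatten_time(ds)
  M1 <- fusnatsynth:::flatten_time(out$dataset)
  expect_true(all(colSums(M1^2) <= colSums(M0^2) + 1e-8))
  # a voxel equal to a basis timecourse is removed (centered projection)
  ds2 <- ds
  z <- fusnatsynth:::flatten_time(ds)[, which(!ds$geometry$cortex_mask)] %*%
    out$basis$weights_out[, 1]
  M <- fusnatsynth:::flatten_time(ds2)
  M[, 1] <- z - mean(z)
  ds2$data <- fusnatsynth:::unflatten_time(M, ds2)
  cleaned <- remove_noise_components(ds2, out$basis)
  expect_lt(sum(fusnatsynth:::flatten_time(cleaned)[, 1]^2), 1e-6 * sum((z - mean(z))^2))
})

test_that("scrubbing removes sound-correlated motion but keeps sound responses", {
  gt <- make_ground_truth(n_pairs = 12, K = 4, n_slices = 3,
                          voxels_per_slice = 60, out_voxels_per_slice = 20,
                          gap = "ferret", motion_sd = 2, seed = 30)
  ds <- percent_signal_change(simulate_trials(gt, n_reps = 4, seed = 31))
  out <- scrub_dataset(ds, k = 20)
  mask <- gt$geometry$cortex_mask
  n_t <- dim(ds$data)[3]
  corr_with_motion <- function(d) {
    mean(sapply(1:3, function(s) {
      m <- as.vector(sapply(seq_len(ncol(ds$aux$motion_amp)), function(j)
        ds$aux$motion_amp[s, j] * ds$aux$motion_shape))
      vox <- which(mask & gt$geometry$slice_id == s)
      mean(abs(cor(m, fusnatsynth:::flatten_time(d)[, vox])))
    }))
  }
  raw_corr <- corr_with_motion(ds)
  cln_corr <- corr_with_motion(out$dataset)
  expect_lt(cln_corr, 0.5 * raw_corr)
  # signal preservation: NSE of cleaned windowed responses to the noiseless
  # truth does not exceed that of the raw responses
  truth_resp <- ds$aux$noiseless[mask, ]
  nse_raw <- median(nse_rows(time_average(ds)$values[mask, ], truth_resp))
  nse_cln <- median(nse_rows(time_average(out$dataset)$values[mask, ],
                             truth_resp))
  expect_lte(nse_cln, nse_raw + 0.01)
  # the category-correlated motion striping artifact is attenuated: the
  # natural-minus-synthetic difference map loads less on the planted motion
  # loading pattern after scrubbing
  st <- ds$sound_table
  nat <- which(st$natural)
  syn <- match(st$pair[nat], st$pair[!st$natural]) + sum(st$natural)
  stripe <- function(d) {
    rm_ <- time_average(d)$values
    dm <- rowMeans(rm_[mask, nat] - rm_[mask, syn])
    abs(cor(dm, gt$motion_loading[mask]))
  }
  expect_lt(stripe(out$dataset), stripe(ds))
})
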