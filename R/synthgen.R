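## Synthetic-data generator: trial-structured voxel timecourses with known
## latent components, gamma-shaped hemodynamics, structured noise (repetition,
## slice, and sound-correlated motion shared with out-of-cortex voxels), and a
## configurable natural-vs-synthetic response gap that either grows with
## distance to primary auditory cortex ("human" mode) or is absent ("ferret"
## mode). Every downstream stage of the pipeline can be validated against the
## ground truth planted here.

DEFAULT_CATEGORIES <- c("vocalization", "speech", "music", "other")

#' Construct the latent ground truth for a simulated experiment
#'
#' Draws K latent component response profiles across natural/synthetic sound
#' pairs, non-Gaussian (exponential-tailed) voxel weights, voxel geometry with
#' an in/out-of-cortex mask and distance to the primary auditory cortex (PAC)
#' centroid, a per-voxel natural-vs-synthetic response gap, and per-voxel
#' motion loadings. Everything downstream (trial simulation, denoising,
#' decomposition, spatial statistics) can be checked against this object.
#'
#' @param n_pairs number of natural/matched-synthetic sound pairs (sounds =
#'   2 * n_pairs).
#' @param K number of latent components (>= 1).
#' @param n_slices number of imaging slices (one session each).
#' @param voxels_per_slice in-cortex voxels per slice (laid out on a
#'   `ny x nz` grid, 0.1 mm spacing; slices 0.4 mm apart).
#' @param out_voxels_per_slice out-of-cortex voxels per slice (motion and
#'   noise only, no sound-evoked signal).
#' @param gap `"ferret"` (no natural-vs-synthetic gap) or `"human"` (gap
#'   grows linearly with distance to PAC).
#' @param gap_max gap at the maximal distance, in units of the voxel's
#'   response s.d. across sounds (human mode only).
#' @param gap_categories categories of natural sounds receiving the gap
#'   (default: all).
#' @param snr ratio of the s.d. (across sounds) of a voxel's windowed
#'   noiseless response to the s.d. of repetition noise in a single-trial
#'   windowed average.
#' @param slice_noise_frac s.d. of the slice-shared noise relative to
#'   repetition noise.
#' @param motion_sd s.d. scale of the motion artifact, in units of the
#'   median windowed signal s.d.; 0 disables motion.
#' @param motion_category category whose trials evoke systematically larger
#'   movement (sound-correlated motion confound).
#' @param amp median voxel signal s.d. in fractional signal-change units.
#' @param weights optional voxels x K weight matrix overriding the random
#'   draw (e.g. Laplacian weights for decomposition tests).
#' @param categories recycled category labels for the sound pairs.
#' @param seed integer seed; all draws funnel through it.
#' @return object of class `ground_truth`; see fields in the implementation.
#' @export
make_ground_truth <- function(n_pairs = 30, K = 8, n_slices = 6,
                              voxels_per_slice = 100, out_voxels_per_slice = 25,
                              gap = c("ferret", "human"), gap_max = 1.2,
                              gap_categories = NULL, snr = 1,
                              slice_noise_frac = 0.5,
                              motion_sd = 1, motion_category = "vocalization",
                              amp = 0.05, weights = NULL,
                              categories = DEFAULT_CATEGORIES, seed = 1) {
  gap <- match.arg(gap)
  n_sounds <- 2L * n_pairs
  n_in <- n_slices * voxels_per_slice
  n_out <- n_slices * out_voxels_per_slice
  n_vox <- n_in + n_out
  if (K < 1 || K > min(n_sounds, n_in))
    stop("invalid dimensions: need 1 <= K <= min(sounds, in-cortex voxels)")

  with_seed(seed, {
    ## Geometry: slices along x (0.4 mm), in-slice grid in (y, z) at 0.1 mm.
    ny <- ceiling(sqrt(voxels_per_slice))
    nz <- ceiling(voxels_per_slice / ny)
    grid <- expand.grid(y = seq_len(ny), z = seq_len(nz))[seq_len(voxels_per_slice), ]
    coords_in <- do.call(rbind, lapply(seq_len(n_slices), function(s)
      cbind(x = (s - 1) * 0.4, y = (grid$y - 1) * 0.1, z = (grid$z - 1) * 0.1)))
    coords_out <- do.call(rbind, lapply(seq_len(n_slices), function(s)
      cbind(x = (s - 1) * 0.4,
            y = stats::runif(out_voxels_per_slice, 0, (ny - 1) * 0.1),
            z = (nz - 1) * 0.1 + 0.3 + stats::runif(out_voxels_per_slice, 0, 0.2))))
    coords <- rbind(coords_in, coords_out)
    slice_id <- c(rep(seq_len(n_slices), each = voxels_per_slice),
                  rep(seq_len(n_slices), each = out_voxels_per_slice))
    cortex_mask <- c(rep(TRUE, n_in), rep(FALSE, n_out))
    pac_center <- c(mean(range(coords_in[, "x"])) / 2,
                    mean(range(coords_in[, "y"])) / 2)
    distance_to_pac <- sqrt((coords[, "x"] - pac_center[1])^2 +
                            (coords[, "y"] - pac_center[2])^2)
    distance_to_pac[!cortex_mask] <- NA_real_

    ## Sound table: matched natural/synthetic pairs with category labels.
    cat_per_pair <- rep_len(categories, n_pairs)
    sound_table <- data.frame(
      sound = seq_len(n_sounds),
      name = c(sprintf("nat%02d", seq_len(n_pairs)),
               sprintf("syn%02d", seq_len(n_pairs))),
      category = rep(cat_per_pair, 2),
      natural = rep(c(TRUE, FALSE), each = n_pairs),
      pair = rep(seq_len(n_pairs), 2),
      stringsAsFactors = FALSE)

    ## Latent profiles: shared between a natural sound and its matched
    ## synthetic (the model-matched null), drawn per pair.
    P_pair <- matrix(stats::rnorm(n_pairs * K), n_pairs, K)
    ## Deterministic strength spectrum (1.3 down to 0.7 of the mean): real
    ## component variances decay gently, and no planted component is ever
    ## vanishingly weak relative to the others.
    strength <- if (K > 1) seq(1.3, 0.7, length.out = K) else 1
    P_pair <- sweep(P_pair, 2, strength, "*")
    ## One component is category-selective so that category/feature analyses
    ## have planted structure to find.
    sel_cat <- categories[1]
    P_pair[, K] <- P_pair[, K] + 2 * strength[K] * as.numeric(cat_per_pair == sel_cat)
    profiles <- rbind(P_pair, P_pair)   # sounds x K (natural rows then synthetic)

    ## Weights: exponential-tailed (log-normal minus its median), positive
    ## excess kurtosis -> identifiable by entropy-based decomposition.
    if (is.null(weights)) {
      W_in <- matrix(exp(stats::rnorm(n_in * K, sd = 0.7)), n_in, K)
      W_in <- sweep(W_in, 2, apply(W_in, 2, stats::median), "-")
    } else {
      W_in <- as.matrix(weights)
      stopifnot(nrow(W_in) == n_in, ncol(W_in) == K)
      kurt <- apply(W_in, 2, function(w) {
        s <- stats::sd(w)
        if (!is.finite(s) || s == 0) return(-3)   # constant: degenerate
        z <- (w - mean(w)) / s
        mean(z^4) - 3
      })
      if (all(kurt <= 0))
        warning("no component has positive excess kurtosis; ",
                "decomposition is not identifiable for these weights")
    }
    W <- rbind(W_in, matrix(0, n_out, K))  # out-of-cortex: no evoked signal

    ## Scale weights so the median voxel signal s.d. across sounds is `amp`.
    A0 <- W_in %*% t(profiles)
    sd_v <- apply(A0, 1, stats::sd)
    scale_fac <- amp / stats::median(sd_v)
    W <- W * scale_fac

    ## Natural-vs-synthetic gap per voxel (units of voxel response s.d.).
    natsynth_gap <- numeric(n_vox)
    if (gap == "human") {
      dmax <- max(distance_to_pac, na.rm = TRUE)
      natsynth_gap[cortex_mask] <-
        gap_max * distance_to_pac[cortex_mask] / dmax
    }
    if (is.null(gap_categories)) gap_categories <- categories

    ## Motion loading: nonzero both inside and outside cortex.
    motion_loading <- stats::rnorm(n_vox)

    ## Noise scales, expressed in fractional signal-change units. Repetition
    ## noise is i.i.d. per sample; averaging over the n_win window samples
    ## divides its s.d. by sqrt(n_win), so the per-sample s.d. realising the
    ## requested windowed SNR is amp * kw * sqrt(n_win) / snr, with kw the
    ## mean hemodynamic kernel gain inside the averaging window.
    timing <- list(dt = 1, baseline = 7, stimulus = 10, post = 3,
                   window = c(3, 11))
    tt <- seq(0, timing$baseline + timing$stimulus + timing$post - 1)
    kern <- evoked_timecourse(tt, timing)
    win <- tt - timing$baseline >= timing$window[1] &
           tt - timing$baseline < timing$window[2]
    kw <- mean(kern[win])
    n_win <- sum(win)
    sigma_rep <- if (snr > 0) amp * kw * sqrt(n_win) / snr else 0
    ## Motion artifacts in awake imaging are large relative to evoked
    ## responses; the baseline scale (motion_sd = 1) is three times the
    ## evoked peak amplitude.
    noise_spec <- list(rep = sigma_rep,
                       slice = slice_noise_frac * sigma_rep,
                       motion = motion_sd * 3 * amp * kw)

    geometry <- structure(list(coords = coords, cortex_mask = cortex_mask,
                               slice_id = slice_id,
                               distance_to_pac = distance_to_pac,
                               pac_center = pac_center,
                               subject_id = "sim", hemisphere = "left"),
                          class = "voxel_geometry")

    structure(list(
      component_profiles = profiles, component_weights = W,
      natsynth_gap = natsynth_gap, gap_mode = gap,
      gap_categories = gap_categories,
      noise_spec = noise_spec, motion_loading = motion_loading,
      motion_category = motion_category,
      sound_table = sound_table, geometry = geometry, timing = timing,
      n_slices = n_slices, voxels_per_slice = voxels_per_slice,
      out_voxels_per_slice = out_voxels_per_slice,
      selective_category = sel_cat, amp = amp, snr = snr, seed = seed
    ), class = "ground_truth")
  })
}

## Peak-normalized evoked timecourse: gamma kernel convolved with the
## stimulus boxcar on the trial grid (times in s from trial onset).
evoked_timecourse <- function(times, timing) {
  dt <- timing$dt
  tk <- seq(0, 12, by = dt)
  h <- hemodynamic_kernel(tk)
  box <- as.numeric(times >= timing$baseline &
                    times < timing$baseline + timing$stimulus)
  ev <- stats::convolve(box, rev(h), type = "open")[seq_along(times)]
  if (max(ev) > 0) ev <- ev / max(ev)
  ev
}

## Raised-cosine movement bump covering the stimulus period (motion happens
## while the animal reacts to the sound).
motion_timecourse <- function(times, timing) {
  on <- timing$baseline; off <- on + timing$stimulus
  m <- numeric(length(times))
  inside <- times >= on & times < off
  m[inside] <- 0.5 - 0.5 * cos(2 * pi * (times[inside] - on) / (off - on))
  m
}

#' Noiseless windowed response matrix implied by a ground truth
#'
#' The voxels x sounds matrix of time-averaged (3-11 s window) noiseless
#' responses, including the natural-vs-synthetic gap: the oracle against
#' which denoising and NSE statistics are validated.
#'
#' @param truth a `ground_truth`.
#' @return voxels x sounds numeric matrix (fractional signal-change units).
#' @export
true_response_matrix <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  timing <- truth$timing
  tt <- seq(0, timing$baseline + timing$stimulus + timing$post - 1)
  kern <- evoked_timecourse(tt, timing)
  win <- tt - timing$baseline >= timing$window[1] &
         tt - timing$baseline < timing$window[2]
  kw <- mean(kern[win])
  A <- truth$component_weights %*% t(truth$component_profiles)
  A <- apply_gap(A, truth)
  A * kw
}

## Add the planted natural-vs-synthetic gap to an amplitude matrix.
apply_gap <- function(A, truth) {
  st <- truth$sound_table
  sd_v <- apply(A, 1, stats::sd)
  tgt <- which(st$natural & st$category %in% truth$gap_categories)
  if (length(tgt) > 0 && any(truth$natsynth_gap != 0))
    A[, tgt] <- A[, tgt] + outer(truth$natsynth_gap * sd_v, rep(1, length(tgt)))
  A
}

#' Simulate a trial-structured dataset from a ground truth
#'
#' Each trial timecourse is the hemodynamic kernel convolved with the 10 s
#' stimulus boxcar, scaled by the voxel's latent response to the sound, plus
#' a motion artifact shared between in- and out-of-cortex voxels (per-trial
#' half-normal amplitude whose scale is larger for `motion_category` trials),
#' plus slice-shared and independent repetition noise, all riding on a
#' per-voxel raw baseline (power-Doppler arbitrary units). Each slice is an
#' independent session: its noise, motion, and baseline draws are
#' independent of other slices.
#'
#' @param truth a `ground_truth`.
#' @param n_reps repetitions of each sound (per slice).
#' @param seed integer seed (independent of the ground-truth seed).
#' @return object of class `trial_dataset`: `data` (voxels x trials x time,
#'   raw a.u.), `trial_table`, `sound_table`, `timing`, `geometry`, and an
#'   `aux` list holding oracles (noiseless windowed responses, per-slice
#'   motion traces and amplitudes).
#' @export
simulate_trials <- function(truth, n_reps = 4, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  timing <- truth$timing
  tt <- seq(0, timing$baseline + timing$stimulus + timing$post - 1)
  n_t <- length(tt)
  st <- truth$sound_table
  n_sounds <- nrow(st)
  n_trials <- n_sounds * n_reps
  geom <- truth$geometry
  n_vox <- nrow(geom$coords)
  ns <- truth$noise_spec

  kern <- evoked_timecourse(tt, timing)
  mshape <- motion_timecourse(tt, timing)

  A <- truth$component_weights %*% t(truth$component_profiles)
  A <- apply_gap(A, truth)

  trial_table <- data.frame(trial = seq_len(n_trials),
                            sound = rep(seq_len(n_sounds), n_reps),
                            rep = rep(seq_len(n_reps), each = n_sounds))
  motion_scale <- ifelse(st$category[trial_table$sound] == truth$motion_category &
                           st$natural[trial_table$sound], 2, 0.5)

  with_seed(seed, {
    baseline <- 100 * exp(stats::rnorm(n_vox, sd = 0.1))
    data <- array(0, dim = c(n_vox, n_trials, n_t))
    motion_amp <- matrix(0, truth$n_slices, n_trials)
    for (s in seq_len(truth$n_slices)) {
      vox <- which(geom$slice_id == s)
      amp_s <- abs(stats::rnorm(n_trials)) * motion_scale * ns$motion
      motion_amp[s, ] <- amp_s
      sig <- A[vox, trial_table$sound, drop = FALSE]          # vox x trials
      evoked <- outer(sig, kern)                               # vox x trials x t
      mot <- outer(truth$motion_loading[vox] %o% amp_s, mshape)
      ## slice-shared physiological fluctuations: low-rank (2 latent white
      ## timecourses per slice) with random voxel loadings, independent
      ## across slices; affects in- and out-of-cortex voxels alike
      r_sl <- 2L
      lat <- array(stats::rnorm(r_sl * n_trials * n_t,
                                sd = ns$slice / sqrt(r_sl)),
                   dim = c(r_sl, n_trials * n_t))
      L_sl <- matrix(stats::rnorm(length(vox) * r_sl), length(vox), r_sl)
      sl_noise <- array(L_sl %*% lat, dim = c(length(vox), n_trials, n_t))
      rep_noise <- array(stats::rnorm(length(vox) * n_trials * n_t,
                                      sd = ns$rep),
                         dim = c(length(vox), n_trials, n_t))
      frac <- evoked + mot + sl_noise + rep_noise
      data[vox, , ] <- baseline[vox] * (1 + frac)
    }
    structure(list(
      data = data, trial_table = trial_table, sound_table = st,
      timing = timing, geometry = geom, units = "raw",
      aux = list(noiseless = true_response_matrix(truth),
                 motion_amp = motion_amp,
                 motion_shape = mshape,
                 motion_loading = truth$motion_loading)
    ), class = "trial_dataset")
  })
}

#' Simulate an ultrafast frame stack for power-Doppler formation
#'
#' Frames are the sum of low-rank, high-energy tissue motion, a spatially
#' sparse blood signal, and white noise; the per-pixel ground-truth blood
#' power is stored so the clutter filter can be validated.
#'
#' @param n_frames number of frames (default 300).
#' @param n_pixels number of pixels.
#' @param tissue_rank rank of the tissue-motion subspace (< n_frames).
#' @param tissue_amp s.d. scale of each tissue component.
#' @param blood_amp s.d. scale of the blood signal in vessel pixels.
#' @param vessel_frac fraction of pixels containing vessels.
#' @param noise_amp white-noise s.d.
#' @param seed integer seed.
#' @return list with `frames` (n_frames x n_pixels), `blood_power`
#'   (per-pixel expected blood energy), `vessel_mask`, and the parameters.
#' @export
simulate_doppler_frames <- function(n_frames = 300, n_pixels = 400,
                                    tissue_rank = 5, tissue_amp = 100,
                                    blood_amp = 1, vessel_frac = 0.1,
                                    noise_amp = 0.05, seed = 1) {
  if (tissue_rank >= n_frames) stop("tissue_rank must be < n_frames")
  with_seed(seed, {
    frames <- matrix(0, n_frames, n_pixels)
    if (tissue_rank > 0) {
      U <- matrix(stats::rnorm(n_frames * tissue_rank), n_frames)
      V <- matrix(stats::rnorm(n_pixels * tissue_rank), n_pixels)
      frames <- frames + tissue_amp * (U %*% t(V)) / sqrt(tissue_rank)
    }
    vessel_mask <- stats::runif(n_pixels) < vessel_frac
    sigma_blood <- ifelse(vessel_mask,
                          blood_amp * (0.5 + stats::runif(n_pixels)), 0)
    frames <- frames + matrix(stats::rnorm(n_frames * n_pixels), n_frames) *
      rep(sigma_blood, each = n_frames)
    if (noise_amp > 0)
      frames <- frames + matrix(stats::rnorm(n_frames * n_pixels,
                                             sd = noise_amp), n_frames)
    list(frames = frames,
         blood_power = n_frames * sigma_blood^2,
         vessel_mask = vessel_mask,
         tissue_rank = tissue_rank, noise_amp = noise_amp, seed = seed)
  })
}

#' Read a simulation configuration from YAML
#'
#' @param path path to a YAML file whose keys match the arguments of
#'   [make_ground_truth()] plus `n_reps` and `trial_seed`.
#' @return named list of configuration values.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}

#' Generate a simulated dataset from a configuration list
#'
#' @param config list as returned by [read_sim_config()].
#' @return a `trial_dataset` (with the `ground_truth` attached as
#'   `attr(, "truth")`).
#' @export
simulate_from_config <- function(config) {
  n_reps <- config$n_reps %||% 4
  trial_seed <- config$trial_seed %||% (config$seed %||% 1)
  gt_args <- config[setdiff(names(config), c("n_reps", "trial_seed"))]
  truth <- do.call(make_ground_truth, gt_args)
  ds <- simulate_trials(truth, n_reps = n_reps, seed = trial_seed)
  attr(ds, "truth") <- truth
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
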