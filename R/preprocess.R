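## Preprocessing: power-Doppler image formation with an SVD clutter filter,
## baseline normalisation to percent signal change, time-window averaging
## into voxel x sound response matrices, and tonotopic best-frequency maps.

#' Power-Doppler image from an ultrafast frame stack
#'
#' Removes the first `n_discard` principal components of the frame stack
#' (computed over the time dimension, components ordered by singular value;
#' these capture high-energy global tissue motion) and returns the per-pixel
#' sum of squared magnitudes of the residual across frames - the blood
#' signal energy, approximately proportional to blood volume.
#'
#' @param frames n_frames x n_pixels numeric matrix (each row one frame).
#' @param n_discard number of leading principal components to discard
#'   (default 55, for 300-frame ensembles).
#' @return numeric vector of per-pixel power (non-negative).
#' @export
power_doppler <- function(frames, n_discard = 55) {
  frames <- as.matrix(frames)
  if (n_discard >= nrow(frames))
    stop("n_discard must be smaller than the number of frames")
  if (n_discard > 0) {
    s <- svd(frames, nu = n_discard, nv = 0)
    frames <- frames - s$u %*% (t(s$u) %*% frames)
  }
  colSums(frames^2)
}

#' Convert raw trial timecourses to percent signal change
#'
#' Per trial, subtracts the trial's mean signal over the pre-stimulus
#' baseline window; then divides by the voxel's mean baseline signal across
#' the whole session. Units become fractional change relative to baseline
#' perfusion. Voxels with a non-positive session baseline are flagged
#' invalid (set to `NA`).
#'
#' @param dataset a `trial_dataset` in raw units.
#' @return the dataset with `data` in fractional signal-change units,
#'   `units = "psc"`, and a logical `valid_voxels` entry.
#' @export
percent_signal_change <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (identical(dataset$units, "psc"))
    warning("dataset already in percent-signal-change units; normalizing again")
  tt <- seq(0, dim(dataset$data)[3] - 1) * dataset$timing$dt
  base_idx <- which(tt < dataset$timing$baseline)
  if (length(base_idx) == 0) stop("empty baseline window")
  trial_base <- apply(dataset$data[, , base_idx, drop = FALSE], c(1, 2), mean)
  session_base <- rowMeans(trial_base)
  valid <- is.finite(session_base) & session_base > 0
  out <- dataset$data
  out <- out - as.vector(trial_base)           # recycles over time (dim 3)
  out <- out / ifelse(valid, session_base, NA_real_)
  dataset$data <- out
  dataset$units <- "psc"
  dataset$valid_voxels <- valid
  dataset
}

#' Time-averaged voxel x sound response matrix
#'
#' Averages each trial's response over a post-onset time window (samples
#' whose time lies in `[window[1], window[2])` seconds after stimulus
#' onset), then averages over the repetitions selected by `split`.
#' Repetitions are pooled across slices by voxel identity.
#'
#' @param dataset a `trial_dataset` (normally in percent-signal-change
#'   units).
#' @param window numeric length-2: seconds post-onset (default `c(3, 11)`).
#' @param split `"all"`, `"odd"`, `"even"`, or an integer vector of
#'   repetition indices.
#' @return object of class `response_matrix`: list with `values`
#'   (voxels x sounds), `split_id`, `window`, `sound_table`.
#' @export
time_average <- function(dataset, window = c(3, 11), split = "all") {
  stopifnot(inherits(dataset, "trial_dataset"))
  timing <- dataset$timing
  tt <- seq(0, dim(dataset$data)[3] - 1) * timing$dt
  post <- tt - timing$baseline
  win <- post >= window[1] & post < window[2]
  if (!any(win)) stop("window contains no samples")
  reps <- sort(unique(dataset$trial_table$rep))
  sel_reps <- if (is.numeric(split)) {
    split
  } else switch(match.arg(split, c("all", "odd", "even")),
    all = reps, odd = reps[reps %% 2 == 1], even = reps[reps %% 2 == 0])
  keep <- dataset$trial_table$rep %in% sel_reps
  if (!any(keep))
    stop("empty split: no trials for repetitions ",
         paste(sel_reps, collapse = ", "))
  tw <- apply(dataset$data[, keep, win, drop = FALSE], c(1, 2), mean)
  sounds <- dataset$trial_table$sound[keep]
  n_sounds <- nrow(dataset$sound_table)
  values <- vapply(seq_len(n_sounds), function(s)
    rowMeans(tw[, sounds == s, drop = FALSE]), numeric(nrow(tw)))
  values <- matrix(values, nrow = dim(dataset$data)[1])
  dimnames(values) <- list(NULL, dataset$sound_table$name)
  structure(list(values = values,
                 split_id = if (is.numeric(split))
                   paste(split, collapse = ",") else split,
                 window = window,
                 sound_table = dataset$sound_table),
            class = "response_matrix")
}

#' Per-voxel best frequency from pure-tone responses
#'
#' The best frequency of a voxel is the tone frequency evoking the largest
#' windowed response (default window 3-5 s after tone onset, for 2 s tones).
#' Ties are broken toward the lower frequency and flagged.
#'
#' @param tone_dataset a `trial_dataset` whose `sound_table` has a numeric
#'   `frequency` column (Hz); the standard set is 602, 1430, 3400, 8087 and
#'   19234 Hz.
#' @param window seconds post-onset (default `c(3, 5)`).
#' @return list with `best_frequency` (Hz per voxel), `tied` (logical), and
#'   the `frequencies` tested.
#' @export
best_frequency_map <- function(tone_dataset, window = c(3, 5)) {
  stopifnot(inherits(tone_dataset, "trial_dataset"),
            "frequency" %in% names(tone_dataset$sound_table))
  rm_ <- time_average(tone_dataset, window = window, split = "all")
  freqs <- tone_dataset$sound_table$frequency
  o <- order(freqs)
  vals <- rm_$values[, o, drop = FALSE]
  fs <- freqs[o]
  idx <- apply(vals, 1, which.max)   # first maximum -> lowest frequency wins
  tied <- apply(vals, 1, function(v) sum(v == max(v)) > 1)
  if (any(tied))
    message(sum(tied), " voxel(s) had tied best frequencies; ",
            "ties broken toward the lower frequency")
  list(best_frequency = fs[idx], tied = tied, frequencies = fs)
}
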