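# Shared fixtures: small simulated datasets built in code. The "small"
# configuration trades statistical power for speed and is used by unit
# tests; module-level recovery tests build their own larger fixtures.

small_truth <- function(gap = "ferret", seed = 1, ...) {
  make_ground_truth(n_pairs = 8, K = 3, n_slices = 2, voxels_per_slice = 30,
                    out_voxels_per_slice = 10, gap = gap, seed = seed, ...)
}

small_dataset <- function(gap = "ferret", seed = 1, n_reps = 4,
                          trial_seed = seed + 100, ...) {
  simulate_trials(small_truth(gap = gap, seed = seed, ...),
                  n_reps = n_reps, seed = trial_seed)
}

# Split-half windowed responses for in-cortex voxels (voxels x sounds).
split_responses <- function(ps) {
  list(odd = time_average(ps, split = "odd")$values,
       even = time_average(ps, split = "even")$values)
}

# Greedy matching of recovered components to planted ones by |correlation|.
best_match_corr <- function(recovered, planted) {
  cm <- abs(stats::cor(recovered, planted))
  apply(cm, 2, max)
}
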