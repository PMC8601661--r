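---
title: "Methods: denoising and model-matched sound analysis for fUS imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: denoising and model-matched sound analysis for fUS imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusnatsynth)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters, and the choices made
where the design was genuinely open. The package's unit and acceptance
tests compute every empirical claim referenced here; the vignette itself
states no number the tests do not produce.

## The scientific setting

Hemodynamic imaging (fMRI, and functional ultrasound at much finer spatial
grain) measures a temporally smoothed, time-averaged proxy of neural
activity. If a cortical region's response is driven by a particular set of
time-averaged acoustic statistics, then two sounds matched on those
statistics should evoke the same response. Comparing responses to natural
sounds and to synthetic sounds matched on cochlear and spectrotemporal
modulation statistics therefore probes whether a region encodes anything
*beyond* those statistics. The dissimilarity measure is the normalized
squared error (NSE); the pipeline's job is to measure it reliably in noisy,
trial-structured voxel data, to localize it spatially relative to primary
auditory cortex (PAC), and to characterize the underlying response
components.

Sound synthesis itself is out of scope: the package measures statistics of
given stimuli and analyzes responses; it never generates matched audio.

## Trial structure and preprocessing

Trials last 20 s at 1 Hz sampling: 7 s silent baseline, 10 s sound, 3 s
post-stimulus silence. Raw power-Doppler values are converted to fractional
signal change by subtracting each trial's mean baseline and dividing by the
voxel's session-mean baseline (`percent_signal_change()`); the division
makes the result invariant to per-voxel perfusion scale, and the function
deliberately warns and does *not* protect against being applied twice,
because double normalization is a silent error the tests guard explicitly.

Responses are summarized per sound as the mean over a post-onset window,
default 3–11 s, where the hemodynamic response is near its plateau. The
window convention is half-open: a sample is included if its center lies in
`[start, end)` seconds post-onset. This avoids double-counting endpoint
samples at 1 Hz sampling; the continuum limit of the windowed mean is
unaffected (a linear ramp averages to the analytic midpoint, which the
tests verify on a refined grid). Tonotopy uses the same machinery with a
3–5 s window appropriate for 2 s tones, breaking best-frequency ties toward
the lower frequency (logged).

Power-Doppler formation removes the leading principal components of each
300-frame stack (default 55) before summing squared magnitudes; tissue
motion is low-rank and orders of magnitude stronger than blood signal, so
the filter's action is essentially a projection complement. Total output
power is non-increasing in the number of discarded components, which the
tests assert.

## The synthetic-data generator

Every downstream stage is validated against simulations with known ground
truth (`make_ground_truth()` + `simulate_trials()`). The generator's
defaults define the package's reference study conditions:

- **Latent structure.** K = 8 component response profiles across 30
  natural/synthetic sound pairs; each pair shares one profile (the
  model-matched null). Per-component strengths follow a fixed gentle decay
  (1.3 down to 0.7 of the mean), so no planted component is vanishingly
  weak; one component is category-selective to give the category and
  feature analyses planted structure.
- **Weights.** Voxel weights are log-normal minus their median —
  exponential-tailed with positive excess kurtosis, matching the
  identifiability assumption of the entropy-based decomposition. A
  Laplacian alternative can be supplied explicitly.
- **Hemodynamics.** A gamma-variate kernel (shape 3, scale 1 s; ~2 s rise)
  convolved with the 10 s stimulus boxcar. The exact kernel family is not
  critical; any smooth build-up peaking inside the 3–11 s window gives the
  same analyses.
- **Geometry.** 6 coronal slices 0.4 mm apart, 100 in-cortex voxels per
  slice on a 0.1 mm grid plus 25 out-of-cortex voxels; distance-to-PAC is
  Euclidean distance to a designated centroid. (On real data the centroid
  comes from the tonotopic map; here it is planted.)
- **Noise.** Three sources, all seeded. (1) Repetition noise: i.i.d. per
  sample, scaled so that the ratio of windowed single-trial signal s.d. to
  windowed noise s.d. equals the `snr` parameter (default 1 — chosen to
  produce raw split-half reliabilities near 0.45, the regime where
  denoising matters). (2) Slice noise: *low-rank* (two latent white
  timecourses per slice with random voxel loadings, in- and out-of-cortex
  alike), independent across slices since each slice is a separate session.
  The low rank matters: shared physiological fluctuations in real data are
  dominated by a few global modes, and a full-rank shared noise floor would
  be unremovable by any finite number of canonical components. (3) Motion:
  a raised-cosine bump during the sound with per-trial half-normal
  amplitude whose scale is larger for natural vocalization trials
  (reproducing the sound-correlated movement confound), loading on all
  voxels through a random per-voxel gain. Its baseline scale is three times
  the evoked peak amplitude, reflecting how large motion artifacts are in
  awake imaging relative to evoked responses.
- **Natural-vs-synthetic gap.** In "ferret" mode the gap is zero
  everywhere. In "human" mode it rises linearly with distance-to-PAC to
  `gap_max` (default 1.2 response s.d.) at the maximal distance; a 1.2 s.d.
  additive offset yields a true NSE of about 0.42 at the most distal
  voxels, comfortably above the 0.3 the distal-bin checks require.

What the simulations do *not* emulate: vascular anatomy, registration
error, non-stationary noise within a session, temporally correlated
hemodynamic noise, and realistic tonotopic map geometry. Passing tests
demonstrate the *statistical machinery* is correct and well-calibrated
under the stated noise model, not that real data meet that model.

## Denoising part I: canonical-correlation scrubbing

Out-of-cortex voxels cannot contain stimulus-driven cortical signal but do
share motion and global physiological artifacts with cortical voxels, and
the animals move more for some sound categories — so artifact timecourses
are partially sound-locked, and naive removal of anything shared would also
remove genuine responses. The scrub therefore fits canonical correlation
analysis between in- and out-of-cortex *trial residuals* (each trial minus
its sound's across-repetition mean), where reliable sound-locked signal
cancels but trial-varying artifacts survive. The resulting out-of-cortex
spatial filters are then applied to the *full* out-of-cortex data to
reconstruct artifact timecourses on every trial — including their
sound-locked component — and each voxel's least-squares projection onto
their span is subtracted.

Open choices, decided as follows:

- **Which side defines the basis:** the out-of-cortex side, because by
  construction it cannot contain cortical stimulus responses.
- **Regularization:** voxels can outnumber timepoints, so plain CCA is
  ill-posed; each side is whitened with covariance shrinkage (ridge equal
  to `shrinkage` — default 1e-3 — times the mean eigenvalue). In the
  well-posed low-dimensional regime the result matches `stats::cancor` to
  six decimals (tested).
- **k = 20** canonical components by default, exposed as a parameter. In
  the default simulation this accommodates the ~12 slice-noise directions
  plus the ~6 motion directions.

The removal is a projection, so no voxel timecourse norm can increase; on
simulation it cuts the mean absolute correlation between cleaned cortical
voxels and the true motion trace by well over half while leaving the NSE
against the noiseless truth unchanged or better, and it attenuates the
motion-driven striping in natural-minus-synthetic difference maps. All
three are asserted in tests.

## Denoising part II: reliability-biased components (DSS)

Principal components maximize variance; what we want are components that
are *reliable* across repetitions and slices. The procedure: whiten each
repetition × slice matrix (ZCA on the retained subspace; singular values
below 1e-6 of the maximum dropped), average the whitened matrices across
repetitions, concatenate across slices along the voxel dimension, and take
the top-N principal components over time. Whitening equalizes all response
directions first, so after averaging and concatenation the leading
directions are those that survive averaging coherently — the reliable ones.
Denoising projects data onto their span.

Cross-validated component-count selection splits sound *pairs* 75/25
(stratified by category, natural and synthetic always on the same side),
fits components and voxel weights `W` on training sounds only, and denoises
held-out test responses purely through `W` — nothing is refit on test data,
so test-sound whitening transforms are never needed. Reported per
candidate N: median split-half correlation raw, after denoising one split,
after denoising both, and the `sqrt(reliability)` upper bound for the
one-split case.

Two aggregation choices worth stating: the per-voxel split-half correlation
is computed on windowed responses to test sounds; and when the acceptance
checks summarize the cross-validation curve over multiple seeds, they take
the argmax of the seed-averaged curve (individual-seed curves are flat near
the optimum, so their argmax is noisy in a way the averaged curve is not).
Under the default study conditions the averaged curve peaks at the planted
eight components (±1), denoising one split brings the median correlation
within 0.05 of the upper bound, and denoising both splits of the held-out
responses lifts their median split-half correlation from ≈0.5 to ≈0.99
(the README's worked example prints one such table).

## NSE statistics and noise correction

The NSE and its corrected form are described in the README. Numerical
conventions:

- The cross-product term of the corrected NSE is averaged over all four
  split pairings (x<sub>i</sub>, y<sub>j</sub>) — symmetric and lowest
  variance; each pairing is unbiased.
- Negative corrected powers are retained in the algebra (clipping would
  bias group medians), but voxels with non-positive corrected denominators
  are excluded from `valid_mask`, as are voxels at or above the 0.4
  test–retest gate.
- A single-repeat condition is supported by borrowing the noise power of
  the repeated condition (`noise_corrected_nse(x1, x2, y1)`).
- The spatial correlation profile correlates split A of voxel i with split
  B of voxel j across sounds, symmetrized; the 0 mm bin is test–retest
  reliability. τ75 subtracts the profile minimum (removing globally shared
  baseline), then solves for 25% of the zero-distance value by linear
  interpolation at the first crossing.

## Component decomposition and cross-species prediction

The decomposition PCA-reduces the voxel × feature matrix to K dimensions
and then rotates: Jacobi sweeps over column pairs with golden-section line
search on each rotation angle, minimizing the summed histogram entropy of
the weight columns (100 equal-width bins spanning the 1st–99th percentile,
add-one smoothing), best of 10 seeded random restarts. Entropy-minimizing
rotations find maximally non-Gaussian weights; for Gaussian weights the
objective is flat under rotation, so solutions whose weight columns are all
near-Gaussian (|skewness| and |excess kurtosis| below 0.5) are flagged
unidentifiable. Components are sign-fixed (positive weight skewness),
normalized to unit-RMS weights, and ordered by explained variance with the
per-component shares summing to one.

Cross-species prediction regresses each target component profile on all
source profiles with ridge regression: 9 outer folds over sound pairs
(a natural sound and its matched synthetic never straddle a fold), penalty
chosen per outer-training set by nested 9-fold CV over the 201-point
log2-spaced grid 2^-100 … 2^100, predictions assembled out-of-fold.
Explained variance is the sign-preserving square of (1 − NSE): squaring is
never allowed to make a negative 1 − NSE positive, so anti-predictions
remain negative and bootstrap distributions (1000 resamples over sound
pairs, seeded, bit-reproducible) are not biased away from zero. Total
component variance is noise-corrected as `(var(r1 + r2) − var(r1 − r2)) /
4` from two independent measurements, and the NSE itself is only
noise-corrected when the target's test–retest NSE passes the 0.4 gate.

## Acoustic features

The cochleagram uses ~40 log-spaced channels (4th-order gammatone magnitude
responses applied in the Fourier domain; ERB-scaled bandwidths), analytic
envelopes, and power-law compression with exponent 0.3; envelopes are
downsampled to 400 Hz, enough for the fastest (128 Hz) modulation filter.
Modulation energies come from a separable 2D Fourier-domain filterbank:
Gaussian-on-log-frequency transfer functions centered on the nine standard
rates (0.5–128 Hz) and six scales (0.25–8 cyc/oct), applied to the
cochleagram's 2D spectrum; energy is the per-channel s.d. over time of the
filtered cochleagram, averaged across channels. Cochlear energy is the
per-channel time average. Inputs shorter than two periods of a rate flag
that rate unreliable. Per-sound RMS normalization (on by default in
`feature_table()`) makes features amplitude-invariant.

Two physical caveats the tests document: overlapping cochlear filters
spread a pure tone's energy over neighboring channels (the best channel
holds the peak but not >80% of total mass), and cochlear bandwidth smooths
fine spectral ripple, so audio-level ripples near the channel-spacing
Nyquist shift their measured peak downward; the modulation filterbank
itself, tested on a synthetic cochleagram with an exact 2 cyc/oct ripple,
peaks at exactly 2 cyc/oct.

The feature–component association test takes the maximum correlation across
a feature group's columns as its statistic and builds the null by permuting
the sound correspondence (1000 permutations by default); the two-sided
p-value doubles the smaller tail with add-one smoothing, flooring at
2/(n_perm + 1). Its type-I error is at the nominal 5% level (calibration
asserted by simulation).

## Spatial statistics

Surface maps average each vertical voxel column within the cortical mask.
Annular profiles bin voxels by absolute distance-to-PAC (0.5 mm bins for
ferret-scale geometry, 5 mm for human) and report median corrected NSE per
bin; the slope is unweighted OLS over the populated bin medians — absolute
distances are the conservative choice for cross-species slope comparisons,
since any brain-size rescaling would only amplify the contrast. Each
subject's slope is compared to a reference group by an exact two-sided
binomial sign test (ties dropped); a slope below all 12 comparators gives
p = 2 × 0.5¹² ≈ 4.9e-4. Model comparisons bootstrap the across-voxel
median NSE by resampling sound pairs (two-sided overlap p, floored at
2/n_boot). Category-wise NSE restricts the corrected numerator to a
category's pairs while taking the denominator from *all* sounds, so the
normalization cannot absorb genuine category differences, and per-sound
NSE values feed Wilcoxon rank-sum tests between categories (exact for small
tie-free samples, normal approximation with continuity correction
otherwise). Difference maps divide mean natural-minus-synthetic differences
by each voxel's s.d. across all sounds. The video motion index sums
absolute frame-to-frame deviations over an ROI, is baseline-normalized like
the imaging signals, and is divided by the per-session s.d. across sounds
before averaging across sessions, which removes camera gain and angle
differences.

## Problem sizes and determinism

The reference simulation (8 components, 30 pairs, 4 repetitions, 6 × 100
cortical voxels) keeps a full pipeline run — simulation, normalization,
scrub, DSS with a 16-point cross-validation scan — under ten seconds, so
the multi-seed acceptance checks complete in minutes; these sizes are the
package's chosen desk-scale study conditions, not limits of the methods.
All stochastic routines take explicit integer seeds, draw through one
internal RNG scope that restores the caller's random state, and are
bit-reproducible: the same seed gives identical simulations, decompositions,
bootstraps, and permutation p-values across runs.

## Known limitations

- Interfaces persist data through R's native serialization and YAML
  configuration files; no HDF5 container layer is provided.
- The scrub assumes shared noise is low-dimensional; a full-rank shared
  noise floor cannot be projected out by any finite canonical basis (the
  generator documents this regime deliberately).
- Distance-to-PAC in simulations is Euclidean to a planted centroid;
  real-data use requires a tonotopically defined center supplied by the
  user.
- The entropy decomposition needs thousands of voxels for stable histogram
  entropy estimates; with few voxels, restarts disagree and components
  should be treated as exploratory.
- The cochlear front end approximates human-resolution filters; fine
  spectral ripple near the channel Nyquist is smoothed (see above), which
  bounds the usable scale range at the default 40 channels.
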