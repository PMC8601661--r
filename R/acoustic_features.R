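## Acoustic feature extraction: cochleagrams from a log-spaced bandpass
## filterbank with envelope compression, temporal / spectral / joint
## modulation energies from a 2D Fourier-domain modulation filterbank, and
## a max-statistic permutation test for component-feature correlations.

#' Standard modulation filter centers
#'
#' Nine temporal rates (0.5-128 Hz, octave-spaced) and six spectral scales
#' (0.25-8 cycles/octave).
#' @return list with `rates` (Hz) and `scales` (cyc/oct).
#' @export
modulation_centers <- function()
  list(rates = 2^seq(-1, 7), scales = 2^seq(-2, 3))

## 4th-order gammatone magnitude response at frequencies f for center fc.
gammatone_mag <- function(f, fc) {
  erb <- 24.7 * (4.37 * fc / 1000 + 1)
  b <- 1.019 * erb
  (1 + ((f - fc) / b)^2)^(-2)
}

#' Cochleagram of an audio waveform
#'
#' Filters the waveform with a bank of log-spaced bandpass filters
#' approximating cochlear frequency resolution (4th-order gammatone
#' magnitude responses, applied in the Fourier domain), takes the envelope
#' of each band (magnitude of the analytic signal), applies power-law
#' compression (exponent 0.3, mimicking cochlear amplification), and
#' downsamples the envelopes.
#'
#' @param wave numeric vector, mono audio samples.
#' @param rate sample rate in Hz (must be at least twice the top filter
#'   center).
#' @param n_channels number of frequency channels (default 40).
#' @param flim channel center range in Hz; the upper edge is clipped to
#'   0.45 * rate.
#' @param env_rate envelope sample rate in Hz (default 400, enough for
#'   128 Hz modulations).
#' @param compression power-law exponent (default 0.3).
#' @return object of class `cochleagram`: `values` (time x channels,
#'   non-negative), `cf` (center frequencies), `env_rate`,
#'   `channel_spacing_oct` (octaves between adjacent channels).
#' @export
cochleagram <- function(wave, rate, n_channels = 40, flim = c(100, 20000),
                        env_rate = 400, compression = 0.3) {
  if (anyNA(wave) || any(!is.finite(wave))) stop("audio contains NA/Inf")
  n <- length(wave)
  fmax <- min(flim[2], 0.45 * rate)
  if (fmax <= flim[1]) stop("sample rate too low for requested channels")
  cf <- 2^seq(log2(flim[1]), log2(fmax), length.out = n_channels)
  spacing <- log2(cf[2] / cf[1])
  W <- stats::fft(wave)
  freqs <- (seq_len(n) - 1) / n * rate
  pos <- freqs <= rate / 2
  dec <- max(1L, floor(rate / env_rate))
  n_out <- floor(n / dec)
  vals <- matrix(0, n_out, n_channels)
  for (ch in seq_len(n_channels)) {
    H <- numeric(n)
    H[pos] <- gammatone_mag(freqs[pos], cf[ch])
    ## analytic band signal: keep positive frequencies only, doubled
    spec <- W * H
    spec[!pos] <- 0
    dbl <- freqs > 0 & freqs < rate / 2
    spec[dbl] <- 2 * spec[dbl]
    env <- Mod(stats::fft(spec, inverse = TRUE)) / n
    env <- env^compression
    vals[, ch] <- colMeans(matrix(env[seq_len(n_out * dec)], nrow = dec))
  }
  structure(list(values = vals, cf = cf, env_rate = rate / dec,
                 channel_spacing_oct = spacing,
                 compression = compression),
            class = "cochleagram")
}

## Gaussian bump on log2 frequency around center `c0` (on |f|), unit peak;
## constant-Q with ~1 octave half-bandwidth.
log_gauss_bump <- function(f, c0, bw_oct = 1) {
  out <- numeric(length(f))
  nz <- abs(f) > 0
  out[nz] <- exp(-(log2(abs(f[nz]) / c0))^2 / (2 * bw_oct^2))
  out
}

## Precompute the 2D FFT of a cochleagram and the frequency axes of the
## modulation domain (temporal Hz, spectral cyc/oct).
cgram_fft2 <- function(cgram) {
  V <- cgram$values
  nt <- nrow(V); nf <- ncol(V)
  F2 <- t(stats::mvfft(t(stats::mvfft(V))))
  f_t <- ifelse(seq_len(nt) - 1 <= nt / 2, seq_len(nt) - 1,
                seq_len(nt) - 1 - nt) * cgram$env_rate / nt
  f_s <- ifelse(seq_len(nf) - 1 <= nf / 2, seq_len(nf) - 1,
                seq_len(nf) - 1 - nf) / (nf * cgram$channel_spacing_oct)
  list(F2 = F2, f_t = f_t, f_s = f_s, nt = nt, nf = nf)
}

## Filter a cochleagram in the 2D Fourier domain with a separable transfer
## function on temporal frequency (Hz) and spectral frequency (cyc/oct);
## `fft2` from cgram_fft2().
filter_cochleagram_2d <- function(fft2, rate = NULL, scale = NULL,
                                  bw_oct = 1) {
  Ht <- if (is.null(rate)) rep(1, fft2$nt)
        else log_gauss_bump(fft2$f_t, rate, bw_oct)
  Hs <- if (is.null(scale)) rep(1, fft2$nf)
        else log_gauss_bump(fft2$f_s, scale, bw_oct)
  G <- fft2$F2 * Ht
  G <- sweep(G, 2, Hs, "*")
  back <- t(stats::mvfft(t(G), inverse = TRUE)) / fft2$nf
  Re(stats::mvfft(back, inverse = TRUE)) / fft2$nt
}

#' Modulation and cochlear energy features of a cochleagram
#'
#' For each modulation filter (temporal-only, spectral-only, and joint
#' spectrotemporal), filters the cochleagram, takes the standard deviation
#' over time of each frequency channel of the filtered cochleagram, and
#' averages across channels, yielding one energy per filter. Cochlear
#' energy is the time average of each channel.
#'
#' @param cgram a `cochleagram`.
#' @param rates,scales modulation filter centers (defaults:
#'   [modulation_centers()]).
#' @return list with `cochlear` (per-channel energies), `temporal` (per
#'   rate), `spectral` (per scale), `spectrotemporal` (rates x scales
#'   matrix), and `unreliable_rates` (rates with fewer than two periods in
#'   the cochleagram duration).
#' @export
modulation_energy <- function(cgram,
                              rates = modulation_centers()$rates,
                              scales = modulation_centers()$scales) {
  stopifnot(inherits(cgram, "cochleagram"))
  dur <- nrow(cgram$values) / cgram$env_rate
  unreliable <- rates[dur < 2 / rates]
  if (length(unreliable) > 0)
    message("rates flagged unreliable for a ", round(dur, 2),
            " s input: ", paste(unreliable, collapse = ", "), " Hz")
  fft2 <- cgram_fft2(cgram)
  sdt <- function(M) mean(apply(M, 2, stats::sd))
  temporal <- vapply(rates, function(r)
    sdt(filter_cochleagram_2d(fft2, rate = r)), 0)
  spectral <- vapply(scales, function(sc)
    sdt(filter_cochleagram_2d(fft2, scale = sc)), 0)
  st <- outer(seq_along(rates), seq_along(scales),
              Vectorize(function(i, j)
                sdt(filter_cochleagram_2d(fft2, rate = rates[i],
                                          scale = scales[j]))))
  dimnames(st) <- list(paste0(rates, "Hz"), paste0(scales, "cyc_oct"))
  list(cochlear = colMeans(cgram$values),
       temporal = stats::setNames(temporal, paste0(rates, "Hz")),
       spectral = stats::setNames(spectral, paste0(scales, "cyc_oct")),
       spectrotemporal = st,
       unreliable_rates = unreliable)
}

#' Feature table for a set of sounds
#'
#' @param waves list of numeric waveforms.
#' @param rate shared sample rate (Hz).
#' @param normalize if `TRUE` (default), each waveform is RMS-normalized
#'   before analysis so features are amplitude-invariant.
#' @param ... passed to [cochleagram()].
#' @return object of class `feature_table`: `cochlear` (sounds x channels),
#'   `temporal`, `spectral`, `spectrotemporal` matrices, and `all` (their
#'   column-wise concatenation).
#' @export
feature_table <- function(waves, rate, normalize = TRUE, ...) {
  feats <- lapply(waves, function(w) {
    if (normalize) {
      r <- sqrt(mean(w^2)); if (r > 0) w <- w / r
    }
    modulation_energy(cochleagram(w, rate, ...))
  })
  cochlear <- do.call(rbind, lapply(feats, `[[`, "cochlear"))
  temporal <- do.call(rbind, lapply(feats, `[[`, "temporal"))
  spectral <- do.call(rbind, lapply(feats, `[[`, "spectral"))
  st <- do.call(rbind, lapply(feats, function(f) as.vector(f$spectrotemporal)))
  colnames(cochlear) <- paste0("coch_", seq_len(ncol(cochlear)))
  colnames(st) <- as.vector(outer(rownames(feats[[1]]$spectrotemporal),
                                  colnames(feats[[1]]$spectrotemporal),
                                  paste, sep = "_"))
  structure(list(cochlear = cochlear, temporal = temporal,
                 spectral = spectral, spectrotemporal = st,
                 all = cbind(cochlear, temporal, spectral, st)),
            class = "feature_table")
}

#' Max-statistic permutation test of component-feature correlations
#'
#' Correlates each component response profile with every feature column,
#' summarizes each feature group by the maximum correlation across its
#' columns, and assesses significance against a null distribution built by
#' permuting the correspondence between sounds and features (`n_perm`
#' permutations; two-sided p = 2 x the smaller tail's overlap fraction,
#' floored at
#' 2 / (n_perm + 1)). Taking the maximum across frequencies/rates makes a
#' single test per group, immune to multiplicity across columns.
#'
#' @param profiles sounds x K matrix (or `component_set`).
#' @param features a `feature_table`, or a named list of sounds x p feature
#'   matrices (groups tested separately).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame per component x feature group: observed max
#'   correlation, which feature attained it, and the permutation p-value.
#' @export
feature_correlation_test <- function(profiles, features, n_perm = 1000,
                                     seed = 1) {
  P <- if (inherits(profiles, "component_set")) profiles$profiles
       else as.matrix(profiles)
  groups <- if (inherits(features, "feature_table"))
    list(frequency = features$cochlear,
         modulation = cbind(features$temporal, features$spectral,
                            features$spectrotemporal))
  else features
  n <- nrow(P)
  perms <- with_seed(seed, replicate(n_perm, sample.int(n)))
  rows <- list()
  for (gname in names(groups)) {
    Fm <- as.matrix(groups[[gname]])
    stopifnot(nrow(Fm) == n)
    keep <- apply(Fm, 2, stats::sd) > 0
    if (!all(keep)) {
      message(sum(!keep), " constant feature column(s) excluded from group ",
              gname)
      Fm <- Fm[, keep, drop = FALSE]
    }
    Zf <- standardize_cols(Fm)
    for (k in seq_len(ncol(P))) {
      y <- P[, k]
      zy <- (y - mean(y)) / stats::sd(y)
      r_obs <- crossprod(Zf, zy) / (n - 1)
      stat <- max(r_obs)
      Zperm <- matrix(zy[perms], n, n_perm)
      null_stat <- apply(crossprod(Zf, Zperm) / (n - 1), 2, max)
      ## add-one two-sided permutation p: smaller tail, doubled; the floor
      ## 2 / (n_perm + 1) arises when no null sample reaches the statistic
      p <- 2 * min(sum(null_stat >= stat) + 1,
                   sum(null_stat <= stat) + 1) / (n_perm + 1)
      rows[[length(rows) + 1]] <- data.frame(
        component = k, group = gname, max_correlation = stat,
        best_feature = colnames(Fm)[which.max(r_obs)] %||% which.max(r_obs),
        p_value = min(p, 1))
    }
  }
  do.call(rbind, rows)
}
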