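grid_geometry <- function(nx = 4, ny = 4, nz = 3) {
  g <- expand.grid(z = seq_len(nz), y = seq_len(ny), x = seq_len(nx))
  list(coords = cbind(g$x, g$y, g$z),
       cortex_mask = rep(TRUE, nrow(g)),
       distance_to_pac = sqrt((g$x - 1)^2 + (g$y - 1)^2))
}

test_that("surface projection averages columns of voxels", {
  geom <- grid_geometry()
  # depth-varying map: column mean is analytic
  vals <- geom$coords[, 3] * 2 + geom$coords[, 1]
  sp <- surface_projection(vals, geom)
  expect_equal(nrow(sp), 16)
  expect_equal(sp$value, sp$x + 2 * mean(seq_len(3)))
  # depth-constant map: projection equals any single layer
  vals2 <- geom$coords[, 1] + 10 * geom$coords[, 2]
  sp2 <- surface_projection(vals2, geom)
  expect_equal(sp2$value, sp2$x + 10 * sp2$y)
  # empty columns give NA
  vals3 <- vals2; vals3[geom$coords[, 1] == 2] <- NA
  sp3 <- surface_projection(vals3, geom)
  expect_true(all(is.na(sp3$value[sp3$x == 2])))
})

test_that("annular profiles recover planted NSE-distance slopes", {
  geom <- grid_geometry(6, 6, 2)
  # planted linear relation NSE = 0.1 + 0.05 * distance
  vals <- 0.1 + 0.05 * geom$distance_to_pac
  ap <- annular_profile(vals, geom, bin_size = 0.5)
  expect_equal(ap$slope, 0.05, tolerance = 0.05)
  # constant map: slope 0
  ap0 <- annular_profile(rep(0.3, nrow(geom$coords)), geom, bin_size = 0.5)
  expect_equal(ap0$slope, 0, tolerance = 1e-10)
  expect_equal(unique(ap0$median_nse), 0.3)
  # invariant to voxel order and to adding voxels that fail the gate
  perm <- sample(nrow(geom$coords))
  geom_p <- list(coords = geom$coords[perm, ],
                 cortex_mask = geom$cortex_mask[perm],
                 distance_to_pac = geom$distance_to_pac[perm])
  expect_equal(annular_profile(vals[perm], geom_p, 0.5)$median_nse,
               ap$median_nse)
  vals_na <- c(vals, rep(NA_real_, 5))
  geom_na <- list(coords = rbind(geom$coords, matrix(1, 5, 3)),
                  cortex_mask = c(geom$cortex_mask, rep(TRUE, 5)),
                  distance_to_pac = c(geom$distance_to_pac, rep(1, 5)))
  expect_equal(annular_profile(vals_na, geom_na, 0.5)$slope, ap$slope)
})

test_that("sign test reproduces the exact binomial probabilities", {
  humans <- seq(0.02, 0.13, by = 0.01)   # 12 human slopes
  res <- compare_slopes(0.001, humans)
  expect_equal(res$p_value, 2 * 0.5^12, tolerance = 1e-12)
  expect_equal(res$n_below, 0L)
  # ferret at the human median: p ~ 1
  res2 <- compare_slopes(median(humans) + 1e-9, humans)
  expect_gt(res2$p_value, 0.7)
  # single comparator: uninformative
  expect_warning(res3 <- compare_slopes(0.1, 0.2), "uninformative")
  expect_equal(res3$p_value, 1)
})

test_that("bootstrap model comparison recovers a planted model hierarchy", {
  set.seed(80)
  nv <- 100; ns <- 30
  S <- matrix(rnorm(nv * ns), nv)
  mknoise <- function(sd) matrix(rnorm(nv * ns, sd = sd), nv)
  splits <- function(gap) {
    E <- matrix(rnorm(nv * ns), nv)   # model-specific mismatch
    list(X1 = S + mknoise(.1), X2 = S + mknoise(.1),
         Y1 = S + gap * E + mknoise(.1), Y2 = S + gap * E + mknoise(.1))
  }
  models <- list(cochlear = splits(0.9), spectral = splits(0.65),
                 temporal = splits(0.4), spectrotemporal = splits(0.1))
  out <- bootstrap_model_comparison(models, n_boot = 500, seed = 4)
  m <- out$median_nse
  expect_true(m["spectrotemporal"] < m["temporal"] &&
              m["temporal"] < m["spectral"] &&
              m["spectral"] < m["cochlear"])
  expect_true(all(out$p[upper.tri(out$p)] < 0.01))
  # identical models: p ~ 1
  same <- splits(0.5)
  out2 <- bootstrap_model_comparison(list(a = same, b = same),
                                     n_boot = 100, seed = 5)
  expect_equal(out2$p["a", "b"], 1)
})

test_that("category NSE shares its normalization and partitions exactly", {
  set.seed(81)
  nv <- 2; np <- 12
  cats <- rep(c("voc", "speech", "music"), each = 4)
  S <- matrix(rnorm(nv * np), nv)
  X1 <- S; X2 <- S
  Y1 <- S; Y2 <- S
  gap <- matrix(0, nv, np); gap[, cats == "voc"] <- 1.5
  Y1 <- Y1 + gap; Y2 <- Y2 + gap
  out <- category_nse(X1, X2, Y1, Y2, cats)
  expect_gt(out$category_nse["voc"], max(out$category_nse[c("speech", "music")]))
  expect_lt(out$tests["voc", "speech"], 0.05)
  # partition identity: size-weighted category numerators recompose the
  # overall numerator (shared denominator construction)
  n_cat <- table(cats)[names(out$category_nse)]
  overall <- weighted.mean(out$category_nse, n_cat)
  all_out <- category_nse(X1, X2, Y1, Y2, rep("all", np))
  expect_equal(overall, unname(all_out$category_nse["all"]), tolerance = 1e-10)
  # matched categories: NSE ~ 0 everywhere
  out0 <- category_nse(X1, X2, S, S, cats)
  expect_true(all(abs(out0$category_nse) < 1e-10))
  expect_message(category_nse(X1, X2, Y1, Y2, c(rep("a", 11), "b")),
                 "excluding")
})

test_that("difference maps are s.d.-normalized and scale-invariant", {
  set.seed(82)
  nv <- 50; np <- 20
  cats <- rep(c("speech", "other"), each = np / 2)
  nat <- matrix(rnorm(nv * np), nv)
  syn <- nat
  # +1 s.d. planted gap for speech in the distal half of voxels
  distal <- seq_len(nv) > nv / 2
  sdv <- apply(cbind(nat, syn), 1, sd)
  nat[distal, cats == "speech"] <- nat[distal, cats == "speech"] + sdv[distal]
  dm <- difference_map(nat, syn, cats)
  expect_true(all(abs(dm[!distal, ]) < 1e-10))
  expect_equal(mean(dm[distal, "speech"]), 1, tolerance = 0.15)
  expect_true(all(abs(dm[, "other"]) < 1e-10))
  # doubling all responses leaves the map unchanged
  dm2 <- difference_map(2 * nat, 2 * syn, cats)
  expect_equal(dm, dm2, tolerance = 1e-12)
  # natural = synthetic: all-zero map
  expect_true(all(difference_map(syn, syn, cats) == 0))
})

test_that("motion index detects planted sound-evoked movement", {
  set.seed(83)
  np <- 12
  st <- data.frame(sound = 1:(2 * np),
                   category = rep(rep(c("vocalization", "other"), each = np / 2), 2),
                   natural = rep(c(TRUE, FALSE), each = np),
                   pair = rep(seq_len(np), 2))
  fpt <- 20; base_f <- 1:7; stim_f <- 8:17
  n_trials_per_session <- 2 * np
  sessions <- 2
  tab <- data.frame(sound = rep(1:(2 * np), sessions),
                    session = rep(1:sessions, each = n_trials_per_session))
  npix <- 30
  gain <- c(1, 7)   # very different camera gains per session
  frames <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    moving <- st$natural[tab$sound[i]] &
      st$category[tab$sound[i]] == "vocalization"
    amp <- if (moving) 3 else 0.3
    fr <- matrix(rnorm(fpt * npix, sd = 0.2), fpt)  # baseline jitter
    fr[stim_f, ] <- fr[stim_f, ] + matrix(rnorm(length(stim_f) * npix,
                                                sd = amp), length(stim_f))
    fr * gain[tab$session[i]]
  }))
  out <- motion_index(frames, tab, st, fpt, base_f, stim_f)
  mt <- out$motion_table
  voc_nat <- mt$index[mt$natural & mt$category == "vocalization"]
  other <- mt$index[!(mt$natural & mt$category == "vocalization")]
  expect_gt(min(voc_nat), max(other))
  expect_lt(out$natsynth_tests$p_value[
    out$natsynth_tests$category == "vocalization"], 0.05)
  # static video: all indices zero
  out0 <- motion_index(frames * 0, tab, st, fpt, base_f, stim_f)
  expect_true(all(out0$motion_table$index == 0 |
                  is.na(out0$motion_table$index)))
  # session gain invariance: per-session normalization removes the gain, so
  # a single-session analysis at gain 1 matches one at gain 7
  one <- tab$session == 1
  o1 <- motion_index(frames[rep(one, each = fpt), ], tab[one, ], st,
                     fpt, base_f, stim_f)
  frames7 <- frames[rep(one, each = fpt), ] * 7
  o7 <- motion_index(frames7, tab[one, ], st, fpt, base_f, stim_f)
  expect_equal(o1$motion_table$index, o7$motion_table$index,
               tolerance = 1e-10)
})
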