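test_that("binning counts spikes exactly and conserves totals", {
  trials <- toy_trials()
  # neuron 1: known spike times around trial 1 onset; neuron 2 silent
  on <- trials$cue_onset_s[1]
  sp <- toy_spikes(list(c(on - 1.5, on + 0.2, on + 0.7, on + 9.5, on + 11.9,
                          on + 12.5), numeric(0)))
  tens <- bin_firing(sp, trials)
  expect_equal(dim(tens), c(2, 7, 14))
  expect_equal(unname(tens[1, 1, 1]), 1L)  # bin [-2,-1)
  expect_equal(unname(tens[1, 1, 3]), 2L)  # bin [0,1)
  expect_equal(unname(tens[1, 1, 12]), 1L) # bin [9,10)
  expect_equal(unname(tens[1, 1, 14]), 1L) # bin [11,12): 2 s past offset
  # spike at +12.5 falls outside the half-open window
  expect_equal(sum(tens[1, 1, ]), 5)
  expect_true(all(tens[2, , ] == 0))       # silent neuron -> all-zero slice
  # conservation: window totals equal in-window spike counts per trial
  in_win <- sum(sp$spikes$spike_time_s >= on - 2 & sp$spikes$spike_time_s < on + 12)
  expect_equal(sum(tens[1, 1, ]), in_win)
  expect_error(bin_firing(sp, trials, bin_width_s = 3), "whole bins")
})

test_that("a constant-rate Poisson neuron averages to its rate in every bin", {
  cfg <- scaled_config(7, seed = 11) # 112 trials
  trials <- generate_trial_table(cfg)
  beh <- generate_behavior(trials, cfg)
  neurons <- plant_neurons("untuned", "sustained", baseline_hz = 5, gain_hz = 0)
  sp <- simulate_spikes(neurons, trials, beh, cfg, seed = 11)
  tens <- bin_firing(sp, trials)
  per_bin <- apply(tens[1, , , drop = FALSE], 3, mean)
  se <- sqrt(5 / nrow(trials))
  expect_true(all(abs(per_bin - 5) < 3 * se))
})

test_that("outcome alignment uses the scheduled shock offset on omission trials", {
  trials <- toy_trials()
  off <- trials$shock_offset_s[trials$cue == "uncertainty" & !trials$shock_delivered][1]
  sp <- toy_spikes(list(off + c(0.1, 4.5, 9.9, 10.2)))
  tens <- bin_firing(sp, trials, alignment = "shock_offset")
  expect_equal(dim(tens)[3], 10)
  j <- which(attr(tens, "trials")$shock_offset_s == off)[1]
  expect_equal(sum(tens[1, j, ]), 3) # 10.2 s is outside the 10-s window
})

test_that("baseline z-scoring centers, preserves sign structure, and floors the SD", {
  trials <- toy_trials()
  set.seed(1)
  counts <- array(rpois(2 * 7 * 14, 5), c(2, 7, 14),
                  dimnames = list(c("n0001", "n0002"), trials$trial_id,
                                  paste0("b", 1:14)))
  tens <- toy_tensor(counts, trials)
  z <- normalize_firing(tens)
  expect_equal(attr(z, "normalization"), "baseline_z")
  # stationary Poisson neuron: mean z near 0
  expect_lt(abs(mean(z[1, , ])), 0.5)
  # doubling all counts leaves the z sign pattern unchanged
  z2 <- normalize_firing(toy_tensor(counts * 2L, trials))
  expect_equal(sign(round(z, 6)), sign(round(z2, 6)))
  expect_error(normalize_firing(z), "already normalized")

  # silent baseline, active cue: z governed by the SD floor (0.1 Hz)
  on <- trials$cue_onset_s
  sp <- toy_spikes(list(as.vector(outer(c(0.5, 0.25, 0.75), on, "+"))))
  t2 <- bin_firing(sp, trials)
  z3 <- normalize_firing(t2)
  expect_equal(unname(z3[1, 1, 3]), 3 / 0.1) # 3 Hz bin, baseline 0 +/- floor
  expect_true(all(z3[1, , attr(t2, "time") < 0] == 0))
})

test_that("outcome tensors can borrow pre-cue baselines from a cue tensor", {
  cfg <- fast_config(n_neurons = 4, seed = 12)
  s <- simulate_session(cfg)
  cue_t <- bin_firing(s$spikes, s$trials)
  out_t <- bin_firing(s$spikes, s$trials, alignment = "shock_offset")
  expect_error(normalize_firing(out_t), "baseline")
  z <- normalize_firing(out_t, baseline_from = cue_t)
  expect_equal(attr(z, "normalization"), "baseline_z")
  expect_true(all(is.finite(z)))
})

test_that("condition averaging is the identity for single trials and label invariant", {
  trials <- toy_trials(n_danger = 1, n_us = 1, n_uo = 1, n_safety = 1)
  set.seed(2)
  counts <- array(rpois(3 * 4 * 14, 4), c(3, 4, 14),
                  dimnames = list(sprintf("n%04d", 1:3), trials$trial_id,
                                  paste0("b", 1:14)))
  tens <- toy_tensor(counts, trials)
  prof <- condition_average(tens, mode = "outcome")
  expect_equal(dim(prof), c(3, 4 * 14))
  for (i in seq_len(nrow(trials))) {
    cond <- c("danger", "uncertainty_shock", "uncertainty_omission",
              "safety")[i]
    expect_equal(unname(prof[, attr(prof, "condition") == cond]),
                 unname(counts[, i, ]))
  }
  # permuting trial order (with labels) leaves the averages unchanged
  perm <- c(3, 1, 4, 2)
  tens_p <- toy_tensor(counts[, perm, , drop = FALSE], trials[perm, ])
  expect_equal(unclass(condition_average(tens_p, mode = "outcome")),
               unclass(prof))
  # cue mode with default window: 3 conditions x 14 bins = 42 features
  prof_cue <- condition_average(tens, mode = "cue")
  expect_equal(ncol(prof_cue), 42)
  # a missing condition is an error
  expect_error(condition_average(toy_tensor(counts[, 1:3, , drop = FALSE],
                                            trials[1:3, ]), mode = "outcome"),
               "missing")
})

test_that("a planted sustained danger responder stands out in its danger block", {
  cfg <- scaled_config(5, seed = 13)
  trials <- generate_trial_table(cfg)
  beh <- generate_behavior(trials, cfg)
  neurons <- plant_neurons("probability", "sustained", baseline_hz = 5,
                           gain_hz = 10)
  sp <- simulate_spikes(neurons, trials, beh, cfg, seed = 13)
  z <- normalize_firing(bin_firing(sp, trials))
  prof <- condition_average(z)
  cue_cols <- attr(prof, "time") >= 0 & attr(prof, "time") < 10
  d <- mean(prof[1, attr(prof, "condition") == "danger" & cue_cols])
  s <- mean(prof[1, attr(prof, "condition") == "safety" & cue_cols])
  expect_gt(d, s + 3)
})

test_that("k-means clustering recovers planted motifs and is deterministic", {
  set.seed(7)
  motif_a <- c(rep(3, 14), rep(0, 28))
  motif_b <- c(rep(0, 28), rep(3, 14))
  x <- rbind(matrix(rep(motif_a, 10), 10, byrow = TRUE),
             matrix(rep(motif_b, 10), 10, byrow = TRUE)) +
    matrix(rnorm(20 * 42, sd = 0.1), 20)
  prof <- toy_profiles(x)
  cm <- cluster_profiles(prof, 2, seed = 3)
  expect_equal(sort(cm$sizes), c(10, 10))
  truth <- rep(1:2, each = 10)
  expect_true(mclust::adjustedRandIndex(cm$assignments, truth) == 1)
  cm2 <- cluster_profiles(prof, 2, seed = 3)
  expect_identical(cm$assignments, cm2$assignments)
  # k = 1: single cluster, centroid is the grand mean
  cm1 <- cluster_profiles(prof, 1, seed = 3)
  expect_equal(unname(cm1$centroids[1, ]), unname(colMeans(x)))
  expect_error(cluster_profiles(prof, 21, seed = 1), "exceeds")
})

test_that("silhouette diagnostics peak at the planted cluster count", {
  set.seed(8)
  motifs <- diag(3)[rep(1:3, each = 8), ] %x% t(rep(1, 14)) * 3
  x <- motifs + matrix(rnorm(24 * 42, sd = 0.15), 24)
  sel <- select_k(toy_profiles(x), k_range = 2:6, seed = 2)
  expect_equal(sel$recommended_k, 3)
  expect_true(all(diff(sel$diagnostics$inertia) <= 1e-8))
})
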