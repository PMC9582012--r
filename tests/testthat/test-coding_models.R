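test_that("cue design carries the shock probabilities and the behavior module's ratios", {
  trials <- toy_trials(n_danger = 3, n_us = 2, n_uo = 3, n_safety = 3)
  set.seed(41)
  beh <- data.frame(trial_id = trials$trial_id, cue = trials$cue,
                    suppression_ratio = runif(nrow(trials)))
  d <- build_cue_design(trials, beh, standardize = FALSE)
  expect_equal(d$P[trials$cue == "danger"], rep(1, 3))
  expect_equal(d$P[trials$cue == "safety"], rep(0, 3))
  expect_equal(d$P[trials$cue == "uncertainty"], rep(0.25, 5))
  expect_equal(d$SR, beh$suppression_ratio) # row-for-row consistency
  # missing-SR trials are dropped; standardization gives mean 0, sd 1
  beh$suppression_ratio[2] <- NA
  dz <- build_cue_design(trials, beh, standardize = TRUE)
  expect_equal(nrow(dz), nrow(trials) - 1)
  expect_equal(mean(dz$SR), 0, tolerance = 1e-12)
  expect_equal(stats::sd(dz$P), 1, tolerance = 1e-12)
  beh$suppression_ratio[] <- NA
  expect_error(build_cue_design(trials, beh), "missing")
})

test_that("outcome design codes shock and prediction error per trial type", {
  trials <- toy_trials()
  d <- build_outcome_design(trials)
  get <- function(type) {
    sel <- switch(type,
      danger = trials$cue == "danger",
      us = trials$cue == "uncertainty" & trials$shock_delivered,
      uo = trials$cue == "uncertainty" & !trials$shock_delivered,
      safety = trials$cue == "safety")
    unique(cbind(d$SHOCK[sel], d$PE[sel]))
  }
  expect_equal(unname(get("danger")), matrix(c(1, 0), 1))
  expect_equal(unname(get("safety")), matrix(c(0, 0), 1))
  expect_equal(unname(get("us")), matrix(c(1, 0.75), 1))
  expect_equal(unname(get("uo")), matrix(c(0, -0.25), 1))
  # indicator coding marks surprising shock only
  di <- build_outcome_design(trials, pe_coding = "indicator")
  expect_equal(di$PE, as.numeric(trials$cue == "uncertainty" &
                                   trials$shock_delivered))
})

test_that("OLS recovers a planted rate = 2 + 3P model and nulls the other regressor", {
  set.seed(42)
  trials <- toy_trials(n_danger = 60, n_us = 30, n_uo = 90, n_safety = 60,
                       spacing = 13, start = 30)
  n_tr <- nrow(trials)
  rate <- 2 + 3 * trials$p
  counts <- array(rpois(n_tr * 14, rep(rate, 14)), c(1, n_tr, 14),
                  dimnames = list("n0001", trials$trial_id, paste0("b", 1:14)))
  tens <- toy_tensor(counts, trials)
  beh <- data.frame(trial_id = trials$trial_id,
                    suppression_ratio = runif(n_tr)) # unrelated to firing
  design <- build_cue_design(trials, beh, standardize = FALSE)
  fit <- fit_unit_encoding(tens, design)
  # bins are independent draws of the same model: compare the across-bin
  # mean beta at 3 standard errors of that mean
  b_p <- mean(fit$beta[1, , "P"])
  expect_lt(abs(b_p - 3), 3 * mean(fit$se[1, , "P"]) / sqrt(14))
  b_sr <- mean(fit$beta[1, , "SR"])
  expect_lt(abs(b_sr), 3 * mean(fit$se[1, , "SR"]) / sqrt(14))
  # a rank-deficient design is refused
  design2 <- design
  design2$SR <- design2$P
  expect_error(fit_unit_encoding(tens, design2), "rank deficient")
})

test_that("cluster beta profiles average units and cancel opposing pairs", {
  trials <- toy_trials(n_danger = 30, n_us = 15, n_uo = 45, n_safety = 30,
                       spacing = 13, start = 30)
  n_tr <- nrow(trials)
  set.seed(43)
  base <- array(rpois(3 * n_tr * 5, 20), c(3, n_tr, 5))
  # neurons 2 and 3: equal and opposite coupling to P
  mod <- outer(trials$p, rep(10, 5))
  base[2, , ] <- rpois(n_tr * 5, 20 + mod)
  base[3, , ] <- rpois(n_tr * 5, pmax(20 - mod, 0))
  dimnames(base) <- list(sprintf("n%04d", 1:3), trials$trial_id,
                         paste0("b", 1:5))
  tens <- toy_tensor(base, trials, window = c(0, 5))
  beh <- data.frame(trial_id = trials$trial_id, suppression_ratio = runif(n_tr))
  fit <- fit_unit_encoding(tens, build_cue_design(trials, beh,
                                                  standardize = FALSE))
  cm <- toy_clusters(stats::setNames(c(1, 2, 2), sprintf("n%04d", 1:3)))
  bp <- cluster_beta_profiles(fit, cm)
  # single-unit cluster: profile equals that unit's betas
  expect_equal(unname(bp[1, , ]), unname(fit$beta[1, , ]))
  # opposing units cancel: the cluster profile is a small fraction of the
  # individual couplings
  expect_lt(max(abs(bp[2, , "P"])), 0.3 * min(abs(fit$beta[2, , "P"])))
  expect_gt(min(abs(fit$beta[2, , "P"])), 7)
})

test_that("signaling PCA separates planted orthogonal motifs and respects block structure", {
  k <- 12; nb <- 14
  set.seed(44)
  m1 <- sin(seq(0, pi, length.out = nb))        # behavior-like motif
  m2 <- exp(-seq(0, 3, length.out = nb))        # probability-like motif
  a <- rnorm(k); b <- rnorm(k)
  prof <- array(0, c(k, nb, 2), dimnames = list(paste0("k", 1:k),
                                                paste0("b", 1:nb),
                                                c("P", "SR")))
  prof[, , "P"] <- outer(b, m2)
  prof[, , "SR"] <- outer(a, m1)
  bp <- structure(prof, time = seq_len(nb) - 3, regressors = c("P", "SR"),
                  class = c("beta_profile", "array"))
  sp <- signaling_pca(bp)
  expect_true(all(diff(sp$var_explained) <= 1e-8))
  # two planted orthogonal signaling motifs load on two leading PCs
  cors <- vapply(1:2, function(pc) {
    c(abs(stats::cor(sp$loading_curves["SR", , pc], m1)),
      abs(stats::cor(sp$loading_curves["P", , pc], m2)))
  }, numeric(2))
  expect_gt(max(cors[1, ]), 0.9)
  expect_gt(max(cors[2, ]), 0.9)

  # clusters with zero probability betas: PC1 loadings vanish on the P block
  prof2 <- prof
  prof2[, , "P"] <- 0
  bp2 <- structure(prof2, time = seq_len(nb) - 3, regressors = c("P", "SR"),
                   class = c("beta_profile", "array"))
  sp2 <- signaling_pca(bp2)
  expect_lt(max(abs(sp2$loading_curves["P", , 1])), 1e-10)
  expect_gt(mean(sp2$loading_curves["SR", , 1] %*% m1), 0) # sign convention
})

test_that("lesioning untuned clusters leaves signaling unchanged within shuffle noise", {
  set.seed(45)
  trials <- toy_trials(n_danger = 12, n_us = 6, n_uo = 18, n_safety = 12,
                       spacing = 13, start = 30)
  n_tr <- nrow(trials)
  nb <- 6
  counts <- array(rpois(8 * n_tr * nb, 8), c(8, n_tr, nb),
                  dimnames = list(sprintf("n%04d", 1:8), trials$trial_id,
                                  paste0("b", 1:nb)))
  # clusters 1-2 carry a probability signal; clusters 3-4 are untuned noise
  for (i in 1:4) counts[i, , ] <- rpois(n_tr * nb, 8 + outer(6 * trials$p, rep(1, nb)))
  tens <- toy_tensor(counts, trials, window = c(0, nb))
  beh <- data.frame(trial_id = trials$trial_id, suppression_ratio = runif(n_tr))
  design <- build_cue_design(trials, beh)
  cm <- toy_clusters(stats::setNames(rep(1:4, each = 2), sprintf("n%04d", 1:8)))
  part <- stats::setNames(c("sig", "sig", "null", "null"), paste0("k", 1:4))
  les <- lesion_network_signaling(tens, cm, part, "null", design,
                                  n_shuffles = 30, seed = 9)
  se <- les$lesioned_ve_sd / sqrt(les$n_shuffles)
  expect_lt(abs(les$delta_ve[1]), 3 * les$lesioned_ve_sd[1] + 1)
  # lesioning the signal network does move PC structure
  les2 <- lesion_network_signaling(tens, cm, part, "sig", design,
                                   n_shuffles = 30, seed = 9)
  expect_gt(abs(les2$delta_ve[1]), abs(les$delta_ve[1]))
})
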