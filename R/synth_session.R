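#' Generate a randomized trial table
#'
#' Builds one session's trial table: the configured counts of danger,
#' uncertainty-shock, uncertainty-omission and safety trials in seeded random
#' order, with inter-trial intervals drawn uniformly around the configured
#' mean. Shock onset is scheduled at cue offset + `shock_delay_s` on every
#' trial; it is delivered only on danger and uncertainty-shock trials, but
#' the scheduled time is retained on all trials so that outcome-period
#' analyses share a common time base.
#'
#' @param config a [synth_config()].
#' @param session_index 1-based session number; combined with the config
#'   seed so each session is reproducible in isolation.
#' @return data.frame with columns `trial_id`, `cue`, `shock_delivered`,
#'   `cue_onset_s`, `cue_offset_s`, `shock_onset_s`, `shock_offset_s`, `p`
#'   (cue shock probability) and `outcome` (0/1 shock delivered).
#' @export
#' @examples
#' trials <- generate_trial_table(synth_config(seed = 1))
#' table(trials$cue, trials$shock_delivered)
generate_trial_table <- function(config, session_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  tc <- config$trial_counts
  types <- rep(names(tc), tc)
  set.seed(derive_seed(config$seed, "trials", session_index))
  types <- sample(types)
  n <- length(types)
  cue <- ifelse(types %in% c("uncertainty_shock", "uncertainty_omission"),
                "uncertainty", types)
  shock_delivered <- types %in% c("danger", "uncertainty_shock")
  iti <- stats::runif(n, config$iti_mean_s - config$iti_jitter_s,
                      config$iti_mean_s + config$iti_jitter_s)
  trial_len <- config$cue_duration_s + config$shock_delay_s +
    config$shock_duration_s
  onset <- config$warmup_s + cumsum(c(0, head(iti, -1) + trial_len))
  data.frame(
    trial_id = seq_len(n),
    cue = cue,
    shock_delivered = shock_delivered,
    cue_onset_s = onset,
    cue_offset_s = onset + config$cue_duration_s,
    shock_onset_s = onset + config$cue_duration_s + config$shock_delay_s,
    shock_offset_s = onset + config$cue_duration_s + config$shock_delay_s +
      config$shock_duration_s,
    p = unname(config$shock_probs[cue]),
    outcome = as.numeric(shock_delivered),
    stringsAsFactors = FALSE
  )
}

#' Simulate nose-poke behavior for one session
#'
#' Draws a session baseline poke rate, then a latent true suppression level
#' `s_trial` per trial (gaussian around the cue's configured mean, clipped to
#' `[0, 1]`). Poke events follow a Poisson process at the baseline rate
#' throughout the session, thinned to `baseline * (1 - s_trial)` during each
#' 10-s cue. Observed suppression ratios are computed downstream from the
#' emitted poke counts, so they carry realistic counting noise around the
#' latent level.
#'
#' @param trials a trial table from [generate_trial_table()].
#' @param config the [synth_config()].
#' @param seed integer seed for this stage.
#' @return list with `pokes` (sorted event times, seconds), `s_trial`
#'   (data.frame `trial_id`, `s_true`) and `baseline_rate_per_min`.
#' @export
generate_behavior <- function(trials, config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(seed, "behavior"))
  rate_min <- stats::rgamma(1, shape = 20,
                            rate = 20 / config$poke_rate_per_min)
  rate_s <- rate_min / 60
  mu <- config$suppression_means[trials$cue]
  s_true <- clip(stats::rnorm(nrow(trials), mu, config$suppression_sd), 0, 1)
  t_end <- max(trials$shock_offset_s) + 60
  n <- stats::rpois(1, rate_s * t_end)
  pokes <- sort(stats::runif(n, 0, t_end))
  # thin pokes inside cue windows by the trial's retention factor 1 - s
  keep <- rep(TRUE, length(pokes))
  u <- stats::runif(length(pokes))
  for (i in seq_len(nrow(trials))) {
    in_cue <- pokes >= trials$cue_onset_s[i] & pokes < trials$cue_offset_s[i]
    keep[in_cue] <- u[in_cue] < (1 - s_true[i])
  }
  list(pokes = pokes[keep],
       s_trial = data.frame(trial_id = trials$trial_id, s_true = s_true),
       baseline_rate_per_min = rate_min)
}

#' Draw a ground-truth neuron population
#'
#' Assigns coding classes by the configured mix (largest-remainder rounding,
#' so planted class counts are exact), a class-appropriate temporal motif,
#' a gamma baseline rate, a gaussian modulation gain (negative for
#' shock-inhibited and cue-inhibited units via the signed kernel), and a
#' region label sampled from the region pool.
#'
#' @inheritParams generate_behavior
#' @return data.frame of class `ground_truth` with one row per neuron:
#'   `neuron_id`, `region`, `baseline_hz`, `motif`, `coding_class`,
#'   `gain_hz`.
#' @export
make_neurons <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(seed, "neurons"))
  n <- config$n_neurons
  # largest-remainder apportionment of classes
  target <- config$coding_mix * n
  cnt <- floor(target)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(target - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  classes <- sample(rep(names(cnt), cnt))
  motifs <- vapply(classes, function(cl) {
    opts <- .class_motifs[[cl]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  baseline <- pmax(stats::rgamma(n, shape = config$baseline_rate_shape,
                                 scale = config$baseline_rate_scale), 0.5)
  gain <- pmax(abs(stats::rnorm(n, config$gain_mean_hz, config$gain_sd_hz)), 1)
  gain[classes == "shock_inhibited"] <- -gain[classes == "shock_inhibited"]
  gain[classes == "untuned"] <- 0
  region <- sample(config$region_names, n, replace = TRUE,
                   prob = config$region_probs)
  out <- data.frame(
    neuron_id = sprintf("n%04d", seq_len(n)),
    region = region,
    baseline_hz = baseline,
    motif = unname(motifs),
    coding_class = classes,
    gain_hz = gain,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ground_truth", "data.frame")
  out
}

# trial-wise drive for a coding class; drive scales the motif kernel
.drive_for <- function(coding_class, trials, s_true) {
  switch(coding_class,
    probability = trials$p,
    behavior = s_true,
    shock = trials$outcome,
    positive_pe = trials$outcome - trials$p,
    tonic_pe = trials$outcome - trials$p,
    shock_inhibited = trials$outcome,
    untuned = rep(0, nrow(trials)),
    fail("unknown coding class: ", coding_class)
  )
}

# TRUE for motifs aligned to shock offset rather than cue onset
.outcome_motif <- function(motif) motif %in% c("phasic_shock", "tonic_postshock")

#' Simulate inhomogeneous-Poisson spike trains
#'
#' Each neuron fires as an inhomogeneous Poisson process with rate
#' `max(0, baseline + gain * kernel(t - event) * drive(trial))`, where the
#' drive is the cue shock probability for probability coders, the latent
#' trial suppression for behavior coders, the shock indicator for shock and
#' shock-inhibited coders, and the prediction-error residual
#' `outcome - p` for phasic and tonic prediction-error coders. Simulation is
#' exact thinning against the envelope `baseline + |gain|`.
#'
#' @param neurons a `ground_truth` table from [make_neurons()].
#' @param trials trial table.
#' @param behavior output of [generate_behavior()] (supplies the latent
#'   per-trial suppression for behavior coders).
#' @param config the [synth_config()].
#' @param seed integer seed for this stage.
#' @return a `spike_set`: list with `spikes` (data.frame `neuron_id`,
#'   `spike_time_s`, sorted within neuron) and `neurons` (id/region table).
#' @export
simulate_spikes <- function(neurons, trials, behavior, config,
                            seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (any(neurons$baseline_hz <= 0)) fail("baseline rates must be positive")
  set.seed(derive_seed(seed, "spikes"))
  t_end <- max(trials$shock_offset_s) + 60
  s_true <- behavior$s_trial$s_true[match(trials$trial_id,
                                          behavior$s_trial$trial_id)]
  out <- vector("list", nrow(neurons))
  for (i in seq_len(nrow(neurons))) {
    nr <- neurons[i, ]
    kern <- motif_kernel(nr$motif, config$cue_duration_s)
    aligns <- if (.outcome_motif(nr$motif)) trials$shock_offset_s else trials$cue_onset_s
    drv <- .drive_for(nr$coding_class, trials, s_true)
    rate_max <- nr$baseline_hz + abs(nr$gain_hz)
    n_cand <- stats::rpois(1, rate_max * t_end)
    ts <- sort(stats::runif(n_cand, 0, t_end))
    idx <- findInterval(ts, aligns)
    mod <- numeric(length(ts))
    hit <- idx >= 1
    if (any(hit)) {
      mod[hit] <- nr$gain_hz * kern(ts[hit] - aligns[idx[hit]]) * drv[idx[hit]]
    }
    rate <- pmax(0, nr$baseline_hz + mod)
    ts <- ts[stats::runif(length(ts)) < rate / rate_max]
    out[[i]] <- if (length(ts)) {
      data.frame(neuron_id = nr$neuron_id, spike_time_s = ts,
                 stringsAsFactors = FALSE)
    } else NULL
  }
  spikes <- do.call(rbind, out)
  if (is.null(spikes)) {
    spikes <- data.frame(neuron_id = character(0), spike_time_s = numeric(0))
  }
  structure(list(spikes = spikes,
                 neurons = neurons[, c("neuron_id", "region")]),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat("Spike set:", nrow(x$neurons), "neurons,",
      nrow(x$spikes), "spikes\n")
  invisible(x)
}

#' Simulate a complete session
#'
#' Convenience wrapper chaining [generate_trial_table()],
#' [generate_behavior()], [make_neurons()] and [simulate_spikes()] under
#' stage-derived seeds.
#'
#' @inheritParams generate_trial_table
#' @return a `fear_session`: list with `trials`, `behavior`, `neurons`
#'   (ground truth), `spikes` (a `spike_set`), `config`, `session_index`.
#' @export
#' @examples
#' s <- simulate_session(synth_config(n_neurons = 5, seed = 1))
#' s
simulate_session <- function(config, session_index = 1L) {
  trials <- generate_trial_table(config, session_index)
  seed_i <- derive_seed(config$seed, "session", session_index)
  behavior <- generate_behavior(trials, config, seed = seed_i)
  neurons <- make_neurons(config, seed = seed_i)
  spikes <- simulate_spikes(neurons, trials, behavior, config, seed = seed_i)
  structure(list(trials = trials, behavior = behavior, neurons = neurons,
                 spikes = spikes, config = config,
                 session_index = session_index),
            class = "fear_session")
}

#' @export
print.fear_session <- function(x, ...) {
  cat("Fear discrimination session", x$session_index, ":",
      nrow(x$trials), "trials,", nrow(x$neurons), "neurons,",
      length(x$behavior$pokes), "pokes\n")
  invisible(x)
}
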