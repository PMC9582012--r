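#' Synthetic 21-region brainstem label set
#'
#' A synthetic stand-in list of 21 brainstem region abbreviations (superior
#' colliculus and periaqueductal gray subdivisions, raphe nuclei and
#' neighbors) used as default region labels by the session generator. The
#' names follow standard rat atlas nomenclature but the set itself is an
#' artifact of this package, not a published inventory.
#'
#' @return character vector of 21 region abbreviations.
#' @export
synthetic_regions <- function() {
  c("SCdg", "SCdw", "SCig", "SCiw", "SCop",
    "PAGdm", "PAGdl", "PAGl", "PAGvl",
    "DRD", "DRV", "DRL", "MnR", "PMnR",
    "CnF", "PPT", "MRN", "RPF", "IC", "LDTg", "VTg")
}

#' Configuration for the synthetic session generator
#'
#' Defaults reproduce the probabilistic fear-discrimination design: 16-trial
#' sessions of 4 danger, 2 uncertainty-shock, 6 uncertainty-omission and 4
#' safety trials (shock probabilities 1.00 / 0.25 / 0.00), 10-s auditory
#' cues, a 0.5-s foot shock delivered 2 s after cue offset on danger and
#' uncertainty-shock trials, a mean inter-trial interval of 3 min, and
#' cue-graded suppression of rewarded nose poking (high to danger,
#' intermediate to uncertainty, low to safety). Spiking neurons mix temporal
#' motifs with condition gains tied to threat probability, trial-wise
#' suppression, shock delivery, or prediction error.
#'
#' The noise model (gamma baseline rates, gaussian trial suppression,
#' inhomogeneous-Poisson spiking) is a stand-in chosen for analytic
#' tractability: real recordings define no generative model, so these
#' distributional choices are artifact defaults, not estimates.
#'
#' @param n_sessions number of sessions the config describes.
#' @param trial_counts named counts per trial type; the uncertainty split
#'   defines the uncertainty shock probability (2/8 = 0.25 by default).
#' @param cue_duration_s,shock_delay_s,shock_duration_s cue length, delay
#'   from cue offset to shock onset, and shock length (seconds).
#' @param iti_mean_s,iti_jitter_s inter-trial interval: uniform on
#'   `iti_mean_s` +/- `iti_jitter_s`.
#' @param warmup_s chamber warm-up before the first trial (seconds).
#' @param n_neurons neurons per session.
#' @param coding_mix proportions of ground-truth coding classes; must sum
#'   to 1 (see [coding_classes()]).
#' @param baseline_rate_shape,baseline_rate_scale gamma parameters of the
#'   baseline firing-rate distribution (Hz); defaults give mean 5 Hz.
#' @param gain_mean_hz,gain_sd_hz distribution of the modulation gain (Hz at
#'   full drive), truncated below at 1 Hz.
#' @param suppression_means named mean true suppression level per cue, in
#'   `[0, 1]`.
#' @param suppression_sd trial-to-trial SD of true suppression.
#' @param poke_rate_per_min mean baseline nose-poke rate (pokes/min).
#' @param region_names,region_probs region label pool and sampling weights
#'   (uniform when `region_probs` is `NULL`).
#' @param seed master integer seed.
#' @return a validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_neurons = 20, seed = 7)
#' cfg$shock_probs
synth_config <- function(n_sessions = 1,
                         trial_counts = c(danger = 4, uncertainty_shock = 2,
                                          uncertainty_omission = 6, safety = 4),
                         cue_duration_s = 10,
                         shock_delay_s = 2,
                         shock_duration_s = 0.5,
                         iti_mean_s = 180,
                         iti_jitter_s = 60,
                         warmup_s = 300,
                         n_neurons = 60,
                         coding_mix = c(probability = 0.20, behavior = 0.15,
                                        shock = 0.10, positive_pe = 0.10,
                                        tonic_pe = 0.10, shock_inhibited = 0.05,
                                        untuned = 0.30),
                         baseline_rate_shape = 2,
                         baseline_rate_scale = 2.5,
                         gain_mean_hz = 8,
                         gain_sd_hz = 2,
                         suppression_means = c(danger = 0.9, uncertainty = 0.5,
                                               safety = 0.05),
                         suppression_sd = 0.2,
                         poke_rate_per_min = 60,
                         region_names = synthetic_regions(),
                         region_probs = NULL,
                         seed = 1L) {
  need <- c("danger", "uncertainty_shock", "uncertainty_omission", "safety")
  if (!all(need %in% names(trial_counts))) {
    fail("trial_counts must name: ", paste(need, collapse = ", "))
  }
  trial_counts <- trial_counts[need]
  if (any(trial_counts < 0) || any(trial_counts != round(trial_counts))) {
    fail("trial_counts must be non-negative integers")
  }
  if (trial_counts["uncertainty_shock"] + trial_counts["uncertainty_omission"] == 0) {
    fail("at least one uncertainty trial is required")
  }
  durs <- c(cue_duration_s, shock_duration_s, iti_mean_s)
  if (any(durs <= 0) || shock_delay_s < 0) fail("durations must be positive")
  if (!setequal(names(coding_mix), coding_classes())) {
    fail("coding_mix must name exactly the classes: ",
         paste(coding_classes(), collapse = ", "))
  }
  if (abs(sum(coding_mix) - 1) > 1e-8) fail("coding_mix must sum to 1")
  if (any(coding_mix < 0)) fail("coding_mix proportions must be >= 0")
  if (!all(c("danger", "uncertainty", "safety") %in% names(suppression_means))) {
    fail("suppression_means must name danger, uncertainty, safety")
  }
  if (any(suppression_means < 0 | suppression_means > 1)) {
    fail("suppression_means must lie in [0, 1]")
  }
  if (n_neurons < 0) fail("n_neurons must be >= 0")
  p_unc <- unname(trial_counts["uncertainty_shock"] /
    (trial_counts["uncertainty_shock"] + trial_counts["uncertainty_omission"]))
  structure(list(
    n_sessions = n_sessions,
    trial_counts = trial_counts,
    cue_duration_s = cue_duration_s,
    shock_delay_s = shock_delay_s,
    shock_duration_s = shock_duration_s,
    iti_mean_s = iti_mean_s,
    iti_jitter_s = iti_jitter_s,
    warmup_s = warmup_s,
    n_neurons = n_neurons,
    coding_mix = coding_mix[coding_classes()],
    baseline_rate_shape = baseline_rate_shape,
    baseline_rate_scale = baseline_rate_scale,
    gain_mean_hz = gain_mean_hz,
    gain_sd_hz = gain_sd_hz,
    suppression_means = suppression_means[c("danger", "uncertainty", "safety")],
    suppression_sd = suppression_sd,
    poke_rate_per_min = poke_rate_per_min,
    region_names = region_names,
    region_probs = region_probs,
    shock_probs = c(danger = 1, uncertainty = p_unc, safety = 0),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic session config:",
      sum(x$trial_counts), "trials/session,",
      x$n_neurons, "neurons, seed", x$seed, "\n")
  cat("  trial mix:", paste(names(x$trial_counts), x$trial_counts,
                            sep = "=", collapse = ", "), "\n")
  cat("  shock probabilities:", paste(names(x$shock_probs),
                                      signif(x$shock_probs, 3),
                                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}
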