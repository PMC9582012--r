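# Compact session settings for tests: short ITIs and warm-up keep simulated
# sessions a few minutes long while preserving the 20-s pre-cue baseline.
fast_config <- function(..., seed = 1L) {
  synth_config(iti_mean_s = 40, iti_jitter_s = 8, warmup_s = 60,
               seed = seed, ...)
}

# a fast config whose trial counts are scaled m-fold (keeps the 4:2:6:4 mix)
scaled_config <- function(m, ..., seed = 1L) {
  synth_config(trial_counts = c(danger = 4, uncertainty_shock = 2,
                                uncertainty_omission = 6, safety = 4) * m,
               iti_mean_s = 30, iti_jitter_s = 5, warmup_s = 60,
               ..., seed = seed)
}

# hand-built ground-truth population (bypasses make_neurons for planted
# recovery designs)
plant_neurons <- function(coding_class, motif, baseline_hz = 5,
                          gain_hz = 5, region = "SCdg") {
  n <- length(coding_class)
  out <- data.frame(
    neuron_id = sprintf("n%04d", seq_len(n)),
    region = rep_len(region, n),
    baseline_hz = rep_len(baseline_hz, n),
    motif = rep_len(motif, n),
    coding_class = coding_class,
    gain_hz = rep_len(gain_hz, n),
    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

# wrap a counts array (neurons x trials x bins) as a firing_tensor
toy_tensor <- function(counts, trials, window = c(-2, 12), bin_width_s = 1,
                       alignment = "cue_onset", normalization = "none") {
  nb <- dim(counts)[3]
  structure(counts, window = window, bin_width_s = bin_width_s,
            alignment = alignment,
            time = window[1] + bin_width_s * (seq_len(nb) - 1),
            trials = trials, normalization = normalization,
            class = "firing_tensor")
}

# profile matrix built directly from a numeric matrix
toy_profiles <- function(x, conditions = NULL, time = NULL) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("n%04d", seq_len(nrow(x)))
  structure(x, condition = conditions, time = time, mode = "cue",
            class = c("profile_matrix", "matrix"))
}

# cluster model from known assignments (for planted-network designs)
toy_clusters <- function(assignments) {
  k <- max(assignments)
  structure(list(k = k, assignments = assignments,
                 centroids = NULL,
                 sizes = as.integer(table(factor(assignments, 1:k))),
                 tot_withinss = NA_real_, seed = NA_integer_),
            class = "cluster_model")
}

# minimal trial table with given per-type counts, evenly spaced
toy_trials <- function(n_danger = 2, n_us = 1, n_uo = 2, n_safety = 2,
                       spacing = 60, start = 60) {
  type <- c(rep("danger", n_danger), rep("uncertainty_shock", n_us),
            rep("uncertainty_omission", n_uo), rep("safety", n_safety))
  n <- length(type)
  cue <- ifelse(grepl("uncertainty", type), "uncertainty", type)
  onset <- start + spacing * (seq_len(n) - 1)
  p <- c(danger = 1, uncertainty = 0.25, safety = 0)[cue]
  data.frame(trial_id = seq_len(n), cue = cue,
             shock_delivered = type %in% c("danger", "uncertainty_shock"),
             cue_onset_s = onset, cue_offset_s = onset + 10,
             shock_onset_s = onset + 12, shock_offset_s = onset + 12.5,
             p = unname(p),
             outcome = as.numeric(type %in% c("danger", "uncertainty_shock")),
             stringsAsFactors = FALSE)
}

# spike_set from a list of per-neuron spike-time vectors
toy_spikes <- function(times_by_neuron, region = "SCdg") {
  ids <- sprintf("n%04d", seq_along(times_by_neuron))
  sp <- do.call(rbind, lapply(seq_along(ids), function(i) {
    if (!length(times_by_neuron[[i]])) return(NULL)
    data.frame(neuron_id = ids[i], spike_time_s = sort(times_by_neuron[[i]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(sp)) {
    sp <- data.frame(neuron_id = character(0), spike_time_s = numeric(0))
  }
  structure(list(spikes = sp,
                 neurons = data.frame(neuron_id = ids,
                                      region = rep_len(region, length(ids)),
                                      stringsAsFactors = FALSE)),
            class = "spike_set")
}
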