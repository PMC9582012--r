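#' Bin spike trains around an alignment event
#'
#' Counts spikes per neuron, trial and time bin in a window relative to cue
#' onset (default window -2 to +12 s, i.e. 2 s before onset through 2 s
#' after the 10-s cue's offset, in 1-s bins) or relative to (scheduled)
#' shock offset (default 0 to +10 s). On trials without shock the scheduled
#' shock-offset time (cue offset + delay + shock duration) is used so all
#' trial types share a time base.
#'
#' @param spikes a `spike_set` (see [simulate_spikes()] / [read_session()]).
#' @param trials trial table.
#' @param alignment `"cue_onset"` or `"shock_offset"`.
#' @param window numeric `(start, end)` in seconds relative to the event;
#'   defaults depend on alignment.
#' @param bin_width_s bin width in seconds; must divide the window evenly.
#' @return a `firing_tensor`: 3-d array `neurons x trials x bins` of spike
#'   counts with attributes `window`, `bin_width_s`, `alignment`, `time`
#'   (bin start times), `trials` (the trial table) and `normalization`.
#' @export
bin_firing <- function(spikes, trials,
                       alignment = c("cue_onset", "shock_offset"),
                       window = NULL, bin_width_s = 1) {
  alignment <- match.arg(alignment)
  if (is.null(window)) {
    window <- if (alignment == "cue_onset") c(-2, 12) else c(0, 10)
  }
  nb <- (window[2] - window[1]) / bin_width_s
  if (abs(nb - round(nb)) > 1e-9 || nb < 1) {
    fail("bin_width_s must divide the window into >= 1 whole bins")
  }
  nb <- as.integer(round(nb))
  align_t <- if (alignment == "cue_onset") trials$cue_onset_s else trials$shock_offset_s
  ids <- spikes$neurons$neuron_id
  x <- array(0L, dim = c(length(ids), nrow(trials), nb),
             dimnames = list(ids, trials$trial_id,
                             paste0("b", seq_len(nb))))
  st <- split(spikes$spikes$spike_time_s, spikes$spikes$neuron_id)
  for (i in seq_along(ids)) {
    ts <- st[[ids[i]]]
    if (is.null(ts) || !length(ts)) next
    ts <- sort(ts)
    # binary search for each trial's in-window spike range
    i0 <- findInterval(align_t + window[1], ts, left.open = TRUE)
    i1 <- findInterval(align_t + window[2], ts, left.open = TRUE)
    for (j in seq_len(nrow(trials))) {
      if (i1[j] > i0[j]) {
        rel <- ts[(i0[j] + 1):i1[j]] - align_t[j]
        x[i, j, ] <- tabulate(floor((rel - window[1]) / bin_width_s) + 1L, nb)
      }
    }
  }
  structure(x, window = window, bin_width_s = bin_width_s,
            alignment = alignment,
            time = window[1] + bin_width_s * (seq_len(nb) - 1),
            trials = trials, normalization = "none",
            class = "firing_tensor")
}

#' @export
print.firing_tensor <- function(x, ...) {
  d <- dim(x)
  cat("Firing tensor:", d[1], "neurons x", d[2], "trials x", d[3], "bins;",
      "aligned to", attr(x, "alignment"), "window",
      paste(attr(x, "window"), collapse = ".."), "s;",
      "normalization:", attr(x, "normalization"), "\n")
  invisible(x)
}

#' Baseline z-score normalization of a firing tensor
#'
#' Per neuron, firing rates are z-scored against the mean and SD of the
#' pre-event baseline bins (bin start < 0) pooled across trials, with an SD
#' floor to avoid division blow-ups for near-silent baselines. Outcome-
#' aligned tensors whose window contains no pre-event bins can borrow the
#' baseline statistics of a second, cue-aligned tensor via `baseline_from`.
#'
#' @param tensor a `firing_tensor` of raw counts.
#' @param sd_floor_hz minimum baseline SD (in Hz-equivalent rate units).
#' @param baseline_from optional second `firing_tensor` (same neurons, raw
#'   counts, containing pre-event bins) supplying the baseline statistics.
#' @return the tensor with values replaced by baseline z-scores and
#'   `normalization = "baseline_z"`.
#' @export
normalize_firing <- function(tensor, sd_floor_hz = 0.1, baseline_from = NULL) {
  stopifnot(inherits(tensor, "firing_tensor"))
  if (attr(tensor, "normalization") != "none") {
    fail("tensor is already normalized")
  }
  src <- if (is.null(baseline_from)) tensor else baseline_from
  base_bins <- which(attr(src, "time") < 0)
  if (length(base_bins) < 2) {
    fail("need >= 2 pre-event baseline bins (supply baseline_from)")
  }
  if (!identical(dimnames(src)[[1]], dimnames(tensor)[[1]])) {
    fail("baseline_from must contain the same neurons")
  }
  rate <- tensor / attr(tensor, "bin_width_s")
  base_rate <- src[, , base_bins, drop = FALSE] / attr(src, "bin_width_s")
  m <- apply(base_rate, 1, mean)
  s <- pmax(apply(base_rate, 1, stats::sd), sd_floor_hz)
  z <- sweep(sweep(rate, 1, m, "-"), 1, s, "/")
  attributes(z) <- attributes(tensor)
  attr(z, "normalization") <- "baseline_z"
  z
}

# condition label per trial: 3 cue conditions or 4 outcome trial types
.trial_conditions <- function(trials, mode = c("cue", "outcome")) {
  mode <- match.arg(mode)
  if (mode == "cue") {
    factor(trials$cue, levels = c("danger", "uncertainty", "safety"))
  } else {
    lab <- ifelse(trials$cue == "uncertainty",
                  ifelse(trials$shock_delivered, "uncertainty_shock",
                         "uncertainty_omission"),
                  trials$cue)
    factor(lab, levels = c("danger", "uncertainty_shock",
                           "uncertainty_omission", "safety"))
  }
}

#' Trial-averaged condition profile matrix
#'
#' Averages a firing tensor over trials within condition and concatenates
#' the per-condition time courses into one feature vector per neuron, in
#' fixed condition order: danger, uncertainty, safety (cue mode) or danger,
#' uncertainty-shock, uncertainty-omission, safety (outcome mode). With the
#' default cue window this yields 3 conditions x 14 bins = 42 features.
#'
#' @param tensor a `firing_tensor` (normalized or raw).
#' @param mode `"cue"` or `"outcome"`.
#' @return a `profile_matrix`: neurons x (conditions x bins) matrix with
#'   attributes `condition` (per column), `time` (per column) and `mode`.
#' @export
condition_average <- function(tensor, mode = c("cue", "outcome")) {
  mode <- match.arg(mode)
  cond <- .trial_conditions(attr(tensor, "trials"), mode)
  if (any(is.na(cond))) fail("trials contain unknown cue labels")
  if (any(table(cond) == 0)) {
    fail("every condition needs >= 1 trial; missing: ",
         paste(levels(cond)[table(cond) == 0], collapse = ", "))
  }
  tvec <- attr(tensor, "time")
  blocks <- lapply(levels(cond), function(cc) {
    sl <- tensor[, cond == cc, , drop = FALSE]
    apply(sl, c(1, 3), mean)
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(levels(cond), function(cc) {
    paste0(cc, ".", dimnames(tensor)[[3]])
  }))
  structure(out,
            condition = rep(levels(cond), each = dim(tensor)[3]),
            time = rep(tvec, length(levels(cond))),
            mode = mode, class = c("profile_matrix", "matrix"))
}

#' K-means functional clustering of condition profiles
#'
#' Clusters neurons on their normalized condition-bin profiles with k-means
#' (Euclidean distance, k-means++-like multi-restart via `nstart`), seeded
#' for reproducibility.
#'
#' @param x a `profile_matrix` (neurons x features).
#' @param k number of clusters (`1 <= k <= n_neurons`).
#' @param seed integer seed.
#' @param nstart number of random restarts (default 50).
#' @return a `cluster_model`: list with `k`, `assignments` (named integer
#'   vector neuron -> cluster), `centroids`, `sizes`, `tot_withinss`,
#'   `seed`.
#' @export
cluster_profiles <- function(x, k, seed = 1L, nstart = 50) {
  if (k < 1) fail("k must be >= 1")
  if (k > nrow(x)) fail("k exceeds the number of neurons")
  set.seed(derive_seed(seed, "kmeans", k))
  km <- stats::kmeans(unclass(x), centers = k, nstart = nstart,
                      iter.max = 100)
  assignments <- stats::setNames(km$cluster, rownames(x))
  structure(list(k = k, assignments = assignments,
                 centroids = km$centers, sizes = unname(km$size),
                 tot_withinss = km$tot.withinss, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Cluster model: k =", x$k, "| sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Diagnostics for choosing the number of clusters
#'
#' Runs k-means over a range of k and reports within-cluster inertia and
#' mean silhouette width; the recommended k maximizes the silhouette.
#' Published analyses of this design settled on 21 cue clusters and 11
#' outcome clusters at full (1812-neuron) scale; those remain available by
#' passing k explicitly to [cluster_profiles()].
#'
#' @param x a `profile_matrix`.
#' @param k_range integer vector of candidate k (each in `[2, n - 1]`).
#' @param seed integer seed.
#' @param nstart restarts per k.
#' @return list with `diagnostics` (data.frame `k`, `inertia`,
#'   `silhouette`) and `recommended_k`.
#' @export
select_k <- function(x, k_range = 2:12, seed = 1L, nstart = 25) {
  k_range <- as.integer(k_range)
  if (any(k_range < 2) || any(k_range >= nrow(x))) {
    fail("k_range must lie in [2, n_neurons - 1]")
  }
  d <- stats::dist(unclass(x))
  rows <- lapply(k_range, function(k) {
    cm <- cluster_profiles(x, k, seed = seed, nstart = nstart)
    sil <- cluster::silhouette(unname(cm$assignments), d)
    data.frame(k = k, inertia = cm$tot_withinss,
               silhouette = mean(sil[, "sil_width"]))
  })
  diagnostics <- do.call(rbind, rows)
  list(diagnostics = diagnostics,
       recommended_k = diagnostics$k[which.max(diagnostics$silhouette)])
}
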