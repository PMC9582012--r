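# % variance explained by PC1 of a mean-centered matrix (rows = neurons)
pc1_var_explained <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  tot <- sum(xc^2)
  if (tot <= 0) fail("matrix has zero variance")
  d <- svd(xc, nu = 0, nv = 0)$d
  100 * d[1]^2 / sum(d^2)
}

#' Population PCA of condition firing profiles
#'
#' PCA with neurons as observations and condition-bin features as variables
#' (mean-centered, unscaled). PC1's sign is fixed so that its mean loading
#' over the danger-condition bins is positive, making loadings and
#' contributions comparable across runs.
#'
#' @param x a `profile_matrix` from [condition_average()].
#' @return a `pc_result`: list with `loadings` (features x components),
#'   `scores` (neurons x components), `var_explained` (% per component,
#'   non-increasing), plus the column `condition`/`time` attributes of `x`.
#' @export
population_pca <- function(x) {
  if (nrow(x) < 2 || ncol(x) < 2) fail("need >= 2 neurons and >= 2 features")
  if (all(apply(x, 2, stats::sd) == 0)) fail("matrix has zero variance")
  p <- stats::prcomp(unclass(x), center = TRUE, scale. = FALSE)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  cond <- attr(x, "condition")
  ref <- if (!is.null(cond) && "danger" %in% cond) cond == "danger" else TRUE
  if (mean(p$rotation[ref, 1]) < 0) {
    p$rotation[, 1] <- -p$rotation[, 1]
    p$x[, 1] <- -p$x[, 1]
  }
  structure(list(loadings = p$rotation, scores = p$x, var_explained = ve,
                 condition = cond, time = attr(x, "time")),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat("Population PCA:", ncol(x$loadings), "components; PC1 explains",
      sprintf("%.1f%%", x$var_explained[1]), "of variance\n")
  invisible(x)
}

#' Shuffle-based per-cluster PC1 variance attribution
#'
#' For each cluster in turn, the feature vectors of its member neurons are
#' shuffled (independent within-neuron permutation of the condition-bin
#' profile, destroying temporal/condition structure while preserving each
#' neuron's marginal values) while all other clusters are left intact; PCA
#' is re-run and PC1's % variance explained recorded. Repeated `n_shuffles`
#' times per cluster, the cluster's contribution is
#' `delta_ve = ve_complete - mean(ve_shuffled)`, and the per-unit
#' contribution divides that by cluster size.
#'
#' @param x a `profile_matrix`.
#' @param clusters a `cluster_model` covering all rows of `x`.
#' @param n_shuffles shuffles per cluster (default 1000).
#' @param seed integer seed.
#' @return a `contribution_table` data.frame: `cluster`, `size`, `delta_ve`
#'   (percentage points), `per_unit_contribution`, `shuffle_sd`,
#'   `n_shuffles`, `seed`; attribute `ve_complete`.
#' @export
cluster_pc_contribution <- function(x, clusters, n_shuffles = 1000,
                                    seed = 1L) {
  if (n_shuffles < 1) fail("n_shuffles must be >= 1")
  if (!identical(sort(names(clusters$assignments)), sort(rownames(x)))) {
    fail("clusters must cover exactly the rows of x")
  }
  ve_complete <- pc1_var_explained(x)
  asg <- clusters$assignments[rownames(x)]
  out <- vector("list", clusters$k)
  for (cl in seq_len(clusters$k)) {
    members <- which(asg == cl)
    if (!length(members)) fail("cluster ", cl, " is empty")
    set.seed(derive_seed(seed, "contrib", cl))
    ve_shuf <- vapply(seq_len(n_shuffles), function(s) {
      xs <- x
      for (i in members) xs[i, ] <- x[i, sample.int(ncol(x))]
      pc1_var_explained(xs)
    }, numeric(1))
    out[[cl]] <- data.frame(
      cluster = cl, size = length(members),
      delta_ve = ve_complete - mean(ve_shuf),
      per_unit_contribution = (ve_complete - mean(ve_shuf)) / length(members),
      shuffle_sd = stats::sd(ve_shuf),
      n_shuffles = n_shuffles, seed = seed)
  }
  res <- do.call(rbind, out)
  attr(res, "ve_complete") <- ve_complete
  class(res) <- c("contribution_table", "data.frame")
  res
}

#' Danger-onset firing latency per neuron
#'
#' Trial-averaged danger PSTH in fine bins, z-scored against the pre-cue
#' baseline (with an SD floor); the latency is the start time of the first
#' run of at least `consec` consecutive bins after onset with `|z|`
#' exceeding `z_thresh`. Neurons without such a run are censored (`NA`).
#'
#' @param spikes a `spike_set`.
#' @param trials trial table (danger trials required).
#' @param fine_bin_s fine PSTH bin width (s).
#' @param z_thresh threshold in baseline SD units.
#' @param consec required run length in bins.
#' @param window peri-onset window (s); must include pre-onset baseline.
#' @param sd_floor_hz baseline SD floor (Hz).
#' @return data.frame `neuron_id`, `latency_s` (`NA` when censored).
#' @export
danger_onset_latency <- function(spikes, trials, fine_bin_s = 0.05,
                                 z_thresh = 2, consec = 3,
                                 window = c(-2, 12), sd_floor_hz = 0.1) {
  dtr <- trials[trials$cue == "danger", , drop = FALSE]
  if (!nrow(dtr)) fail("no danger trials")
  tens <- bin_firing(spikes, dtr, alignment = "cue_onset", window = window,
                     bin_width_s = fine_bin_s)
  tvec <- attr(tens, "time")
  psth <- apply(tens, c(1, 3), mean) / fine_bin_s # neurons x bins, Hz
  base <- tvec < 0
  if (sum(base) < 2) fail("window must include >= 2 pre-onset baseline bins")
  post <- which(tvec >= 0)
  lat <- apply(psth, 1, function(r) {
    m <- mean(r[base])
    s <- max(stats::sd(r[base]), sd_floor_hz)
    z <- abs((r[post] - m) / s) >= z_thresh
    runs <- rle(z)
    ends <- cumsum(runs$lengths)
    hit <- which(runs$values & runs$lengths >= consec)
    if (!length(hit)) return(NA_real_)
    tvec[post[ends[hit[1]] - runs$lengths[hit[1]] + 1]]
  })
  data.frame(neuron_id = rownames(psth), latency_s = unname(lat),
             stringsAsFactors = FALSE)
}

#' Cluster mean danger latencies
#'
#' @param latencies output of [danger_onset_latency()].
#' @param clusters a `cluster_model`.
#' @return data.frame `cluster`, `n_defined`, `mean_latency_s` (`NA` when a
#'   cluster has no uncensored neuron).
#' @export
cluster_latencies <- function(latencies, clusters) {
  asg <- clusters$assignments[latencies$neuron_id]
  do.call(rbind, lapply(seq_len(clusters$k), function(cl) {
    v <- latencies$latency_s[asg == cl]
    v <- v[!is.na(v)]
    data.frame(cluster = cl, n_defined = length(v),
               mean_latency_s = if (length(v)) mean(v) else NA_real_)
  }))
}

#' Regression of PC1 contribution on danger latency
#'
#' Ordinary least squares of per-unit PC1 contribution on cluster mean
#' danger latency; clusters with censored (undefined) mean latency are
#' excluded. Short-latency clusters carrying the ordered cue signal show up
#' as a negative slope.
#'
#' @param latencies output of [cluster_latencies()].
#' @param contributions a `contribution_table`.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
latency_contribution_regression <- function(latencies, contributions) {
  d <- merge(latencies, contributions, by = "cluster")
  d <- d[!is.na(d$mean_latency_s), ]
  if (nrow(d) < 3) fail("need >= 3 clusters with a defined mean latency")
  if (stats::sd(d$per_unit_contribution) < 1e-10) {
    # constant contribution: no association by construction
    return(list(slope = 0, intercept = mean(d$per_unit_contribution),
                r_squared = 0, p_value = 1, n = nrow(d)))
  }
  fit <- stats::lm(per_unit_contribution ~ mean_latency_s, data = d)
  sm <- summary(fit)
  r2 <- sm$r.squared
  p <- sm$coefficients[2, 4]
  if (is.nan(r2)) {
    r2 <- 0
    p <- 1
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       p_value = p,
       n = nrow(d))
}
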