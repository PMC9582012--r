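#' Per-trial nose-poke rates
#'
#' Counts pokes in the 20-s pre-cue baseline window `[onset - 20, onset)` and
#' in the 10-s cue window `[onset, onset + 10)` (half-open, so a poke exactly
#' at onset is counted once, in the cue window) and converts each count to a
#' per-minute rate: baseline count x 3, cue count x 6.
#'
#' @param pokes sorted nose-poke event times (seconds).
#' @param cue_onset_s cue onset time of one trial (seconds).
#' @param baseline_window_s,cue_window_s window lengths (seconds).
#' @return named numeric: `baseline_pokes`, `cue_pokes`, `baseline_rate`,
#'   `cue_rate` (rates in pokes/min).
#' @export
#' @examples
#' poke_rates(c(95, 98, 104), cue_onset_s = 100)
poke_rates <- function(pokes, cue_onset_s, baseline_window_s = 20,
                       cue_window_s = 10) {
  if (baseline_window_s <= 0 || cue_window_s <= 0) {
    fail("windows must be positive")
  }
  if (cue_onset_s - baseline_window_s < 0) {
    fail("baseline window extends before session start")
  }
  if (is.unsorted(pokes)) fail("poke times must be sorted")
  b <- sum(pokes >= cue_onset_s - baseline_window_s & pokes < cue_onset_s)
  cu <- sum(pokes >= cue_onset_s & pokes < cue_onset_s + cue_window_s)
  c(baseline_pokes = b, cue_pokes = cu,
    baseline_rate = b * 60 / baseline_window_s,
    cue_rate = cu * 60 / cue_window_s)
}

#' Suppression ratio
#'
#' `(baseline rate - cue rate) / (baseline rate + cue rate)`. A ratio of 1
#' indicates complete suppression of nose poking during the cue; 0 indicates
#' equivalent baseline and cue rates; negative values (cue rate above
#' baseline) are retained, not clipped. When both rates are 0 the ratio is
#' undefined and `NA` is returned.
#'
#' @param baseline_rate,cue_rate non-negative poke rates (any common unit).
#' @return ratio in `[-1, 1]`, or `NA` for 0/0 trials.
#' @export
#' @examples
#' suppression_ratio(6, 0) # complete suppression -> 1
#' suppression_ratio(9, 6) # -> 0.2
suppression_ratio <- function(baseline_rate, cue_rate) {
  if (any(baseline_rate < 0) || any(cue_rate < 0)) {
    fail("rates must be non-negative")
  }
  denom <- baseline_rate + cue_rate
  out <- ifelse(denom == 0, NA_real_, (baseline_rate - cue_rate) / denom)
  out
}

#' Behavior records for every trial of a session
#'
#' Applies [poke_rates()] and [suppression_ratio()] trial by trial.
#'
#' @param pokes sorted poke event times (seconds).
#' @param trials trial table (needs `trial_id`, `cue`, `cue_onset_s`).
#' @inheritParams poke_rates
#' @return data.frame with one row per trial: counts, rates (pokes/min) and
#'   `suppression_ratio` (`NA` on 0/0 trials).
#' @export
behavior_records <- function(pokes, trials, baseline_window_s = 20,
                             cue_window_s = 10) {
  rec <- t(vapply(trials$cue_onset_s, function(on) {
    poke_rates(pokes, on, baseline_window_s, cue_window_s)
  }, numeric(4)))
  out <- data.frame(trial_id = trials$trial_id, cue = trials$cue, rec,
                    stringsAsFactors = FALSE)
  out$suppression_ratio <- suppression_ratio(out$baseline_rate, out$cue_rate)
  out
}

#' Session-level discrimination summary
#'
#' Per-cue mean and SEM of suppression ratios plus a one-way ANOVA of ratio
#' on cue. Trials with an undefined (0/0) ratio are excluded; the number
#' excluded is reported.
#'
#' @param records output of [behavior_records()].
#' @return list with `cue_means` (data.frame `cue`, `n`, `mean`, `sem`),
#'   `f_statistic`, `df`, `p_value`, `n_missing`.
#' @export
session_discrimination_summary <- function(records) {
  ok <- !is.na(records$suppression_ratio)
  n_missing <- sum(!ok)
  rec <- records[ok, ]
  cues <- intersect(c("danger", "uncertainty", "safety"), unique(rec$cue))
  counts <- table(rec$cue)
  if (length(cues) < length(unique(records$cue)) || any(counts < 2)) {
    fail("every cue needs at least 2 trials with a defined ratio")
  }
  cue_means <- do.call(rbind, lapply(cues, function(cu) {
    v <- rec$suppression_ratio[rec$cue == cu]
    data.frame(cue = cu, n = length(v), mean = mean(v), sem = sem(v))
  }))
  dfs <- c(length(cues) - 1, nrow(rec) - length(cues))
  if (stats::sd(rec$suppression_ratio) < 1e-10) {
    # identical ratios everywhere: no effect, F defined as 0
    f <- 0
    p <- 1
  } else {
    fit <- stats::aov(suppression_ratio ~ factor(cue), data = rec)
    tab <- summary(fit)[[1]]
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  list(cue_means = cue_means,
       f_statistic = f,
       df = dfs,
       p_value = p,
       n_missing = n_missing)
}
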