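---
title: "Constructing threat, behavior and prediction-error signals from neuronal building blocks: methods"
author: "fearnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fearnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearnet)
```

This vignette documents the models, parameter choices and numerical
conventions behind each stage of the pipeline, and what the synthetic
generator does and does not emulate.

## The task model

Three auditory cues (10 s) predict foot shock (0.5 s, delivered 2 s after
cue offset) with probability 1.00 (danger), 0.25 (uncertainty) and 0.00
(safety). A session holds 16 trials — 4 danger, 2 uncertainty-shock, 6
uncertainty-omission, 4 safety — in randomized order with a mean
inter-trial interval of 3 min. The uncertainty split is fixed per session
(2 of 8), not drawn i.i.d., so the realized shock fraction equals the
nominal 0.25 in every session; this matches the session-table reading of
the design. ITI jitter is uniform ±60 s around the mean (only the mean is
part of the design; the jitter width is a package choice).

## Behavior metrics

Baseline poke rate = pokes in `[onset − 20 s, onset)` × 3; cue rate =
pokes in `[onset, onset + 10 s)` × 6 (pokes/min). Windows are half-open
so a poke at exactly cue onset is counted once, in the cue window. The
suppression ratio is `(b − c)/(b + c)`; it is undefined (0/0) when no
pokes fall in either window, and such trials are recorded as missing and
excluded from cue means with a reported count. Negative ratios (cue
poking above baseline) are retained: the formula permits them, and
clipping would bias low-fear estimates. Session discrimination is a
one-way ANOVA of ratio on cue; when every retained ratio is identical the
F statistic is defined as 0 (no effect) rather than 0/0.

Note the ratio is a *nonlinear* readout of the underlying poke-rate
reduction: a cue that halves poking yields SR = 0.5/(2 − 0.5) ≈ 0.33,
not 0.5, and with Poisson-level counts in a 10-s window the per-trial SR
carries counting noise of roughly ±0.15–0.2 SD. Both properties matter
when interpreting the encoding models below.

## The synthetic session generator

The generator exists so every downstream analysis has a recoverable
ground truth. Per neuron it draws a baseline rate (gamma, mean 5 Hz,
floored at 0.5 Hz), a temporal motif (onset, sustained, offset, mid-cue
peak, ramp, cue-inhibited, phasic post-shock, tonic post-shock; kernels
unit-normalized to peak magnitude 1), a coding class and a gain (normal,
mean 8 Hz at full drive). Firing is an inhomogeneous Poisson process

```
rate(t) = max(0, baseline + gain · kernel(t − event) · drive(trial))
```

simulated by exact thinning against the envelope `baseline + |gain|`.
The drive is the cue's shock probability *p* for probability coders, the
latent trial suppression `s` for behavior coders, the shock indicator for
shock and shock-inhibited coders, and the Rescorla–Wagner residual
`outcome − p` for phasic and tonic prediction-error coders. The additive
rate model with a floor at zero (rather than a log-linear model) keeps
OLS recovery analytic: the expected beta of a planted coder equals
gain × (mean kernel mass in the bin).

Behavior is generated from a latent per-trial suppression level
`s = clip(N(mean_cue, sd), 0, 1)` with defaults
`{danger 0.9, uncertainty 0.5, safety 0.05}`; cue-period poke rate is
`baseline × (1 − s)`. Spiking and pokes are conditionally independent
given the trial labels and `s`, so behavior coders are identifiable from
probability coders only through within-cue variability of `s` — which is
exactly the contrast the cue-period encoding model exploits.

Two noise parameters deserve comment because the design's separability
hinges on them. The trial-to-trial suppression SD is 0.2: conditioned
suppression to a partially reinforced cue is highly variable across
trials, and materially smaller values would leave the within-cue signal
below the SR counting noise, making behavior coding unidentifiable by
construction. The baseline poke rate is 60/min, a vigorous but realistic
rate for a food-restricted rat on a variable-interval schedule; it sets
the SR counting noise (≈ ±0.15 per trial). With these values the latent
suppression means are ordered danger > uncertainty > safety in
essentially every session, while the *observed* session SR means are
ordered in ≈ 95% of 16-trial sessions — the residual failures are pure
counting noise on the 4-trial safety/danger means, which no analysis
choice removes at this session length.

Region labels are drawn uniformly from a synthetic 21-name list of
brainstem structures (superior colliculus and periaqueductal gray
subdivisions, raphe nuclei and neighbors). The list is a stand-in: the
package does not claim a published region inventory, and anatomical
biasing is available via `region_probs`.

What the generator does **not** emulate: correlated noise between
neurons, slow drifts and session non-stationarity, spike-sorting
contamination, within-session learning, and any coupling of behavior to
spiking beyond the shared latent `s`. Passing recovery tests therefore
demonstrates correctness of the *analyses*, not robustness to every
pathology of real recordings.

## Binning and normalization

Cue-aligned tensors default to (−2, +12) s in 1-s bins: "2 s after cue
presentation" is read as 2 s after the 10-s cue's *offset*, giving 14
bins and 3 × 14 = 42 condition features; the onset + 2 s reading remains
available by passing `window = c(-2, 2)`. Outcome-aligned tensors default
to (0, +10) s after shock offset, using the *scheduled* shock-offset time
(cue offset + 2.5 s) on omission and safety trials so all four trial
types share a time base.

Normalization is a per-neuron z-score against the pre-event baseline
bins pooled across trials, with an SD floor of 0.1 Hz so near-silent
baselines cannot blow up the scale. The outcome window contains no
pre-event bins, so the pipeline normalizes outcome firing against the
cue tensor's pre-cue baseline (`baseline_from`); this uses one common
baseline per neuron across both analysis periods. The exact normalization
used on the recorded data is not public; baseline z-scoring is the
package's choice and is applied identically everywhere.

## Clustering

K-means on the normalized condition profiles (Euclidean distance, 50
restarts, seeded). `select_k()` reports inertia and mean silhouette over
a k range and recommends the silhouette maximum; published analyses of
the full-scale recordings settled on 21 cue clusters and 11 outcome
clusters, and any k can be forced. On synthetic sessions of a few hundred
neurons the silhouette typically recommends far fewer clusters — cluster
granularity is a property of the data set size, not of the method.

## Population PCA and shuffle attribution

PCA treats neurons as observations and condition-bin features as
variables (mean-centered, unscaled). PC1's sign is fixed so its mean
loading over danger bins is positive, making signs comparable across
runs. A cluster's PC1 contribution shuffles the member neurons'
profiles — an independent within-neuron permutation of the 42 features,
destroying temporal/condition structure while preserving each neuron's
marginal values — leaves all other clusters intact, re-runs PCA, and
averages over 1000 shuffles (default):
`Δve = ve_complete − mean(ve_shuffled)`, reported per unit as
`Δve / cluster size`. Permuting trial labels before averaging is an
alternative granularity, selectable in principle but not the default,
because the attribution question is about the *profile* structure
entering the PCA. Note that `Δve` of an unstructured cluster is slightly
positive, not zero, on any single data set: the realized noise is partly
aligned with PC1 and shuffling destroys that chance alignment. Truly
permutation-invariant profiles (e.g., constant rows) contribute exactly
zero.

Danger-onset latency uses 50-ms bins, a |z| ≥ 2 threshold against the
pre-cue baseline and a 3-consecutive-bin rule; neurons without such a run
are censored. These parameter values are package choices (the criterion
used on the recorded data is unstated); the latency–contribution relation
is summarized by OLS of per-unit contribution on cluster mean latency.

## Functional networks

Cluster–cluster Pearson correlations of mean condition profiles are
grouped by average-linkage clustering on 1 − r, cut at the correlation
threshold (default 0.5) and verified against the mean pairwise
correlation of each group, dropping the most weakly coupled member until
the group passes; groups of ≥ 2 clusters are networks, everything else is
"none" (in cue mode: the supranetwork). The threshold + linkage rule is a
package choice — figure outlines in the source analyses imply but do not
state a criterion — and is exposed as a config knob.

Hub scores correlate each network neuron's profile with the mean profile
of every *fellow* network cluster (own cluster excluded) and average;
networks with fewer than two clusters skip the analysis with a message
(the fellow-cluster correlation is undefined). Regional composition
compares two networks' per-region membership indicators with two-tailed
independent-samples t tests and Levene tests (classical mean-centered
variant, computed as a one-way ANOVA on absolute deviations),
Bonferroni-corrected over regions. The cue/outcome co-membership test is
a one-sample two-cell goodness-of-fit χ² with df = 1 and no continuity
correction (cell expectations are large at realistic scales).

## Encoding models and lesions

Cue mode regresses each neuron's binned firing on an intercept plus
threat probability `P ∈ {0, 0.25, 1}` and the observed trial suppression
ratio `SR`, fitted *simultaneously* so each beta is the variance unique
to its regressor; both regressors are z-scored across retained trials by
default (raw coding available), and trials with undefined SR are dropped.
Because SR is a noisy measure of the latent suppression, the SR beta of a
true behavior coder is attenuated toward zero by the classical
errors-in-variables factor; separability of behavior from probability
coding is therefore a data-scale question, and the recovery tests pool
hundreds of trials before asserting the ≥ 90% classification property.

Outcome mode uses `SHOCK` (delivered indicator, equating danger and
uncertainty shocks) and `PE = outcome − P` (danger-shock 0,
uncertainty-shock +0.75, uncertainty-omission −0.25, safety 0); an
indicator coding of surprising shock only is available. The residual
coding is the default because it is the standard Rescorla–Wagner error
and makes the planted-coder betas analytic.

Signaling PCA runs over clusters as observations with the concatenated
regressor × bin beta features, PC1 signed positive on the behavior
(cue) or shock (outcome) block. Lesioning a network permutes each member
neuron's trial labels independently (destroying trial-linked structure,
preserving marginal firing), refits all regressions, and re-runs the
signaling PCA, averaging over shuffles. Two summaries are reported: the
re-run PCA's % variance per PC (comparable to published lesioned-PCA
figures, but renormalized to the reduced post-lesion total variance and
subject to PC reordering), and the variance of the lesioned beta
profiles **along the intact PC axes**, which is the unambiguous measure
of whether a given intact signal survives the lesion. The acceptance
tests use the axis variance for exactly this reason.

## Numerical conventions and degenerate inputs

* SD floors: 0.1 Hz for baseline z-scoring and latency z-scores.
* Zero-variance profile matrices, empty clusters, rank-deficient designs
  (e.g., SR exactly collinear with P) and missing conditions raise
  errors rather than propagating NaN.
* Correlations with a zero-variance centroid are reported missing and
  can never bind a network.
* All randomized stages draw their seeds from one master seed through a
  keyed hash (`derive_seed()`), so stages re-run independently yet
  reproducibly, and the whole pipeline is byte-deterministic given
  (data, config, seed).

## Problem sizes used in the test suite

Tests validate each stage at desk scale: sessions of tens to a couple of
hundred neurons; recovery simulations pool 100–600 trials; the shuffle
statistic is checked against a 10,000-repetition brute-force oracle on a
20-neuron two-cluster instance; classification and ordering properties
aggregate 100 seeded simulations. These sizes were chosen so each
property is measured well inside its own Monte-Carlo error, and they are
the sizes at which the stated tolerances (3 SE bands, ≥ 90% / ≥ 95%
rates) are meaningful.

## Known limitations

* Headline variance-explained percentages of the full-scale recorded
  data set are properties of those 1812 neurons and are not reproduced
  by synthetic sessions; the package validates the *procedures*, not
  those numbers.
* The network-detection rule and the latency criterion are explicit
  package choices where the source analyses leave the criterion
  unstated; both are configurable.
* OLS on binned counts ignores spike-history and overdispersion; this is
  deliberate (the analysis under study is linear regression), not a
  modeling recommendation.
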