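#' Temporal firing motifs
#'
#' The synthetic generator builds each neuron's peri-event rate modulation
#' from a small library of temporal motifs of the kind routinely seen in
#' peri-stimulus histograms: transient onset and offset responses, firing
#' sustained over the cue, a mid-cue peak, a ramp to cue offset, cue-locked
#' inhibition, and phasic or tonic post-shock responses. Each motif is a
#' kernel over peri-event time, zero outside its declared support and
#' unit-normalized so that `max(abs(kernel)) == 1`; a neuron's modulation is
#' `gain * kernel(t - event) * drive(trial)`.
#'
#' Cue motifs (`onset`, `sustained`, `offset`, `u_shaped`, `ramp`,
#' `inhibited`) are aligned to cue onset; outcome motifs (`phasic_shock`,
#' `tonic_postshock`) are aligned to (scheduled) shock offset.
#'
#' @param name one of [motif_names()].
#' @param cue_duration_s cue length in seconds (sets the support of the
#'   cue-locked motifs).
#' @return a vectorized function of peri-event time (seconds) returning the
#'   kernel value.
#' @export
#' @examples
#' k <- motif_kernel("onset")
#' k(c(-1, 0, 0.5, 3))
motif_kernel <- function(name, cue_duration_s = 10) {
  D <- cue_duration_s
  tau <- 0.6 # decay constant of transient responses, s
  f <- switch(name,
    onset = function(t) ifelse(t >= 0 & t < 2, exp(-t / tau), 0),
    sustained = function(t) as.numeric(t >= 0 & t < D),
    offset = function(t) ifelse(t >= D & t < D + 2, exp(-(t - D) / tau), 0),
    u_shaped = function(t) ifelse(t >= 0 & t < D, sin(pi * t / D), 0),
    ramp = function(t) ifelse(t >= 0 & t < D, t / D, 0),
    inhibited = function(t) -as.numeric(t >= 0 & t < D),
    phasic_shock = function(t) ifelse(t >= 0 & t < 1, exp(-t / 0.3), 0),
    tonic_postshock = function(t) as.numeric(t >= 0 & t < 10),
    fail("unknown motif: ", name)
  )
  f
}

#' @rdname motif_kernel
#' @export
motif_names <- function() {
  c("onset", "sustained", "offset", "u_shaped", "ramp", "inhibited",
    "phasic_shock", "tonic_postshock")
}

# motifs available to each coding class
.class_motifs <- list(
  probability     = c("onset", "sustained", "offset", "u_shaped", "ramp", "inhibited"),
  behavior        = c("onset", "sustained", "offset", "u_shaped", "ramp", "inhibited"),
  shock           = "phasic_shock",
  positive_pe     = "phasic_shock",
  tonic_pe        = "tonic_postshock",
  shock_inhibited = "phasic_shock",
  untuned         = "sustained"
)

#' Coding classes of the synthetic generator
#'
#' @return character vector of ground-truth coding class labels.
#' @export
coding_classes <- function() names(.class_motifs)
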