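#' Derive a reproducible sub-seed from a master seed
#'
#' One global seed fans out to per-stage seeds so that pipeline stages can be
#' re-run independently yet reproducibly. The derivation is a small
#' Lehmer-style hash over the key sequence, kept below 2^31 so the result is
#' always a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param ... stage keys (character labels and/or integers, e.g. a session
#'   index) mixed into the hash in order.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "spikes", 3)
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- abs(as.numeric(seed)) %% 2147483647
  for (k in keys) {
    kv <- if (is.character(k)) sum(utf8ToInt(k)) else abs(as.numeric(k))
    h <- (h * 48271 + kv + 1) %% 2147483647
  }
  as.integer(h)
}

# clip to [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

# stop with a consistent prefix for user-facing validation errors
fail <- function(...) stop(..., call. = FALSE)
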