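# Seed plumbing: every randomized operation draws from a child seed derived
# from one top-level seed plus a stage tag, so a whole run is reproducible
# from a single integer and no stage perturbs another's stream.

#' Derive a child seed from a top-level seed and a stage tag
#'
#' Deterministic, platform-independent mapping used throughout the package to
#' split one user-supplied seed into independent per-stage seeds. The result
#' is always a positive 32-bit integer.
#'
#' @param seed Integer top-level seed.
#' @param tag Character tag naming the consumer (e.g. `"lf-noise1"`).
#' @return A positive integer seed.
#' @export
#' @examples
#' derive_seed(1, "phantom")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483563
  h <- 0
  for (b in utf8ToInt(as.character(tag))) h <- (h * 31 + b) %% m
  as.integer(((abs(as.numeric(seed)) %% m) * 69069 + h) %% m + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
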