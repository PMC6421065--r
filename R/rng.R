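#' Derive a per-replicate seed from a root seed
#'
#' All randomness in an experiment flows from a single root seed. Individual
#' replicates use seeds derived by a fixed counter scheme,
#' `(root_seed + 1000003 * counter) mod (2^31 - 2) + 1`, so that any replicate
#' can be reproduced in isolation without rerunning the ones before it.
#'
#' @param root_seed Integer root seed of the experiment.
#' @param counter Non-negative integer replicate counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 0:3)
derive_seed <- function(root_seed, counter) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.numeric(counter))
  m <- 2^31 - 2
  as.integer((root_seed %% m + (1000003 * (counter %% m)) %% m) %% m + 1)
}

# Set the RNG seed if one is supplied; NULL leaves the current stream alone.
seed_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
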