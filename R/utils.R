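#' @keywords internal
"_PACKAGE"

# Root-mean-square of a numeric vector.
rms <- function(x) sqrt(mean(x^2))

# Clamp to [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round a latent rating to the integer 0-10 numeric rating scale.
nrs_round <- function(x) as.integer(round(clip(x, 0, 10)))

# Derive a reproducible child seed from a parent seed and an index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, index) {
  as.integer((abs(as.double(seed)) * 7919 + 104729 * as.double(index) + 17) %%
               2147483646) + 1L
}

# Set the RNG state when a seed is supplied; otherwise leave the stream alone.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
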