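# Internal helpers shared across the package.

# Evaluate `code` with the global RNG temporarily seeded, restoring the
# caller's RNG state afterwards so seeded simulators do not perturb the
# user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Map angles to [0, period).
wrap_angle <- function(theta, period = 180) theta %% period

# Map angular offsets to [-period/2, period/2).
wrap_offset <- function(x, period = 180) ((x + period / 2) %% period) - period / 2

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Relative Frobenius discrepancy with an absolute fallback when the
# denominator is numerically zero.
rel_frobenius <- function(diff, ref, abs_floor = 1e-12) {
  num <- norm(as.matrix(diff), type = "F")
  den <- norm(as.matrix(ref), type = "F")
  if (den < abs_floor) num else num / den
}
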