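# Seed handling: every stochastic entry point takes `seed`. When a seed
# is given, the caller's RNG state is saved and restored, so seeded
# calls never perturb an enclosing simulation.

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    domain_error("`seed` must be a single non-missing number")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a root seed; keeps results below 2^31 so the
# value is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}
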