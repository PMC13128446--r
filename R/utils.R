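# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
localSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
  invisible(NULL)
}

# Derive a per-family sub-seed from the global seed: one global integer seed
# drives a splittable per-generator stream, so adding a generator never
# perturbs the others. Kept below 2^31.
familySeed <- function(seed, family) {
  offsets <- c(bret_plate = 101L, bret_kinetic = 211L,
               binding_kinetic = 307L, apex = 401L, photometry = 503L,
               endpoints = 601L)
  if (!family %in% names(offsets)) stop("unknown family: ", family)
  (as.integer(seed) * 1000L + offsets[[family]]) %% .Machine$integer.max
}

# Trapezoidal integral of y over x.
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
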