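## Internal helpers: seeded evaluation and interval reflection.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NA/NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed) || length(seed) == 0L || is.na(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic sub-stream seed for component k of a run seeded with `seed`.
subSeed <- function(seed, k) {
  if (is.null(seed) || length(seed) == 0L || is.na(seed)) return(NA_real_)
  (as.integer(seed %% 2147483647) + 104729 * k) %% 2147483647
}

# Fold positions into [0, L] by specular reflection at both ends.
reflectInto <- function(x, L) {
  if (L <= 0) stop("reflection interval must have positive length")
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

kBT_pN_nm <- function(temperature = 298) {
  1.380649e-23 * temperature * 1e21  # pN nm
}
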