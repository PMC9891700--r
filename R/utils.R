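# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Generators must be pure functions of (parameters, seed); leaking RNG state
# into the session would break that contract.
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Sample coefficient of variation in percent (n-1 denominator SD, raw scale).
cv_percent <- function(x) {
  m <- mean(x)
  if (m == 0) {
    return(NA_real_)
  }
  100 * stats::sd(x) / m
}

# Mean-one lognormal multiplicative noise with arithmetic CV `cv`.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
      call. = FALSE
    )
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
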