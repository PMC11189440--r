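# internal helpers: deterministic seed forking, logistic pieces

# Derive n child seeds from one master seed without touching the caller's
# RNG stream. Children stay below 2^31 - 1.
fork_seeds <- function(seed, n, salt = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) + as.integer(salt))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run expr with a locally-set seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 35, x, ifelse(x < -35, exp(x), log1p(exp(x))))
}

# mean negative binomial log-likelihood of a logistic model
logistic_nll <- function(intercept, beta, X, y) {
  eta <- drop(intercept + X %*% beta)
  mean(log1pexp(eta) - y * eta)
}
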