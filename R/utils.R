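# Deterministic RNG streams that do not disturb the caller's global
# .Random.seed: every generator takes an explicit seed and draws from its
# own stream.

make_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e
}

rng_eval <- function(rng, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

rint <- function(rng, lo, hi) rng_eval(rng, sample(lo:hi, 1L))
runif_n <- function(rng, n, lo = 0, hi = 1) rng_eval(rng, stats::runif(n, lo, hi))
rnorm_n <- function(rng, n, mean = 0, sd = 1) rng_eval(rng, stats::rnorm(n, mean, sd))
rpois_n <- function(rng, n, lambda) rng_eval(rng, stats::rpois(n, lambda))
rgamma_n <- function(rng, n, shape) rng_eval(rng, stats::rgamma(n, shape))
sample_int <- function(rng, n, k) rng_eval(rng, sample.int(n, k))
sample_vec <- function(rng, x, k, replace = FALSE)
  rng_eval(rng, sample(x, k, replace = replace))
rbern <- function(rng, n, p) rng_eval(rng, stats::runif(n) < p)
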