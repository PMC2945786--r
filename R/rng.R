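# Named RNG substreams.  Every stochastic component draws from its own
# stream derived from (seed, component name), so adding a component
# never perturbs another's draws, and the caller's global RNG state is
# left untouched.

.hash31 <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  h
}

.substream <- function(seed, name) {
  sub <- (as.numeric(seed) %% 2147483629 * 48271 + .hash31(name)) %%
    2147483629
  env <- new.env(parent = emptyenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    if (is.null(env$state)) set.seed(as.integer(sub))
    else assign(".Random.seed", env$state, globalenv())
    expr
  }
  list(
    runif  = function(n, ...) with_state(stats::runif(n, ...)),
    rnorm  = function(n, ...) with_state(stats::rnorm(n, ...)),
    rbinom = function(n, ...) with_state(stats::rbinom(n, ...)),
    sample = function(x, ...) with_state(sample(x, ...)),
    sample_int = function(n, ...) with_state(sample.int(n, ...))
  )
}
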