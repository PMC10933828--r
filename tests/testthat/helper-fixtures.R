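# Small shared fixtures, built once per test run.

tinySpec <- function(...) {
  args <- list(N = 24, V = 343, k = 3, C = 1, sigma_a = 0.1,
               sigma_b = 0.01, sigma_eps = 0.01, sigma_c = 0.02,
               smooth_len = 1, sessions = 2, seed = 42)
  args[names(list(...))] <- list(...)
  do.call(syntheticSpec, args)
}

.fixtures <- new.env(parent = emptyenv())

# memoised cohort so several test files can share one simulation
tinyCohort <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- simulateCohort(tinySpec())
  .fixtures$tiny
}

# random-but-reproducible matrix helper
rmat <- function(n, m, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * m), n, m))
}

# brute-force OLS via explicit normal equations (independent oracle)
normalEquationsSolve <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}
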