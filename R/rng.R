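# Isolated random-number stream.
#
# Every stochastic routine in the package draws from one of these rather
# than from the caller's global RNG, so results are reproducible from
# (config, seed) and the caller's .Random.seed is left untouched.
new_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  with_state <- function(f) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    out
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(function() stats::rbinom(n, size, prob)),
    sample = function(n, size = n) with_state(function() sample.int(n, size)),
    # child stream with a derived seed, for splitting one seed across stages
    spawn = function(offset) new_rng((seed * 1000003 + offset) %% 2147483647)
  )
}

# truncated-normal draws by inverse-CDF; exact and reproducible
rtruncnorm <- function(rng, n, mean, sd, lower, upper) {
  if (lower >= upper) stop("impossible truncation bounds", call. = FALSE)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) stop("truncation bounds carry no probability mass", call. = FALSE)
  u <- rng$runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
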