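# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Used wherever a function needs
# deterministic internal randomness without disturbing the global stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero (so 4.5 -> 5), unlike base round()'s banker
# rounding; the bin-count heuristic depends on this convention.
.roundHalfUp <- function(x) floor(x + 0.5)

.assertScalarNumber <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
    stop(sprintf("'%s' must be a single number >= %s", name, lower),
         call. = FALSE)
  invisible(x)
}

# Column standard deviations without apply() overhead.
.colSds <- function(x) {
  m <- nrow(x)
  if (m < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, mu, "-")^2) / (m - 1L))
}

.msg <- function(...) message(sprintf(...))
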