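#' Evaluate code with a local random seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the prior
#' RNG state so that callers see no side effects.  Every stochastic routine in
#' the package funnels its randomness through this helper, which is what makes
#' fixed-seed outputs bit-identical.
#'
#' @param seed single integer-valued seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed that stays inside 32-bit integer range
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 31L + offset) %% (.Machine$integer.max - 1)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# sample standard deviation (denominator n - 1); the package-wide convention
sample_sd <- function(x) stats::sd(x)
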