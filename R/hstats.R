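#' Hierarchical sample container
#'
#' Nested data for bootstrap inference: a named list mapping each animal to
#' either a numeric vector of unit-level values (two-level data) or a list of
#' numeric vectors of trial-level values per unit (three-level data).
#'
#' @param groups named list, one element per animal.
#' @return Object of class `hier_sample`.
#' @export
hier_sample <- function(groups) {
  if (!is.list(groups) || length(groups) < 1)
    stop("at least one animal is required", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 1))
    stop("every animal must contribute at least one unit", call. = FALSE)
  structure(list(groups = groups,
                 levels = if (is.list(groups[[1]])) 3L else 2L),
            class = "hier_sample")
}

# one bootstrap replicate of the group statistic: resample m animals with
# replacement, then units within each chosen animal (then trials for
# three-level data); the statistic is applied to the pooled resampled values
resample_stat <- function(groups, statistic, three_level, single_animal, m) {
  a <- length(groups)
  chosen <- if (single_animal) seq_len(a) else
    sample.int(a, m, replace = TRUE)
  vals <- lapply(chosen, function(i) {
    g <- groups[[i]]
    u <- length(g)
    picked <- sample.int(u, u, replace = TRUE)
    if (three_level) {
      unlist(lapply(picked, function(k) {
        tv <- g[[k]]
        tv[sample.int(length(tv), length(tv), replace = TRUE)]
      }), use.names = FALSE)
    } else {
      g[picked]
    }
  })
  statistic(unlist(vals, use.names = FALSE))
}

#' Hierarchical bootstrap for a two-group difference
#'
#' Each bootstrap replicate resamples animals with replacement and then units
#' within each chosen animal with replacement (and trials within units for
#' three-level data), computes the group statistic on the pooled resampled
#' values in each group, and records the difference `a - b`.  The two-sided
#' p-value is the sign-crossing probability with add-one smoothing,
#' `p = 2 * min((1 + #{d > 0}) / (1 + B), (1 + #{d < 0}) / (1 + B))` capped
#' at 1, and the confidence interval is taken from the quantiles of the
#' difference distribution.  Resampling animals propagates between-animal
#' variability into the inference, which a pooled test ignores.
#'
#' By default each replicate draws `A - 1` animals (with replacement) from
#' the `A` observed ones: with few animals, drawing `A` understates the
#' between-animal variance by the factor `(A - 1) / A` and inflates the
#' false-positive rate, and the classical `m = n - 1` cluster-bootstrap
#' correction removes that bias.  Set `animal_draws = "A"` for the naive
#' scheme.
#'
#' @param a,b [hier_sample()] objects (plain named lists are accepted).
#' @param statistic summary function of a numeric vector (default `mean`).
#' @param n_boot bootstrap replicates (default 10000).
#' @param animal_draws `"A-1"` (default, variance-corrected) or `"A"` animals
#'   drawn per replicate.
#' @param ci_level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return List of class `hboot_result`: `point_estimate` (observed
#'   difference), `statistic_distribution`, `ci`, `p_two_sided`, `n_boot`.
#' @export
hierarchical_bootstrap <- function(a, b, statistic = mean, n_boot = 10000,
                                   ci_level = 0.95, seed = 1,
                                   animal_draws = c("A-1", "A")) {
  animal_draws <- match.arg(animal_draws)
  if (!inherits(a, "hier_sample")) a <- hier_sample(a)
  if (!inherits(b, "hier_sample")) b <- hier_sample(b)
  three <- a$levels == 3L
  single_a <- length(a$groups) == 1L
  single_b <- length(b$groups) == 1L
  m_of <- function(s) {
    A <- length(s$groups)
    if (animal_draws == "A") A else max(1L, A - 1L)
  }
  m_a <- m_of(a); m_b <- m_of(b)
  if (single_a || single_b)
    warning("a group has a single animal: animal-level uncertainty is ",
            "unidentifiable; resampling units only for that group")
  flatten <- function(s) unlist(s$groups, use.names = FALSE)
  obs <- statistic(flatten(a)) - statistic(flatten(b))
  d <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      resample_stat(a$groups, statistic, three, single_a, m_a) -
        resample_stat(b$groups, statistic, three, single_b, m_b)
    }, numeric(1))
  })
  # ties at zero count toward both sides, so a point-mass distribution at 0
  # (degenerate data) yields p = 1 rather than a spuriously small p
  p_pos <- (1 + sum(d >= 0)) / (1 + n_boot)
  p_neg <- (1 + sum(d <= 0)) / (1 + n_boot)
  alpha <- 1 - ci_level
  structure(list(point_estimate = obs, statistic_distribution = d,
                 ci = unname(quantile(d, c(alpha / 2, 1 - alpha / 2))),
                 p_two_sided = min(1, 2 * min(p_pos, p_neg)),
                 n_boot = n_boot),
            class = "hboot_result")
}

#' Two-sample permutation test
#'
#' Pools the samples, permutes group labels `n_perm` times, and returns the
#' add-one two-sided p-value
#' `p = (1 + #{|stat_perm| >= |stat_obs|}) / (1 + n_perm)`.
#'
#' @param x,y numeric samples.
#' @param statistic function of `(x, y)` (default difference of means).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return List: `statistic` (observed), `p`.
#' @export
permutation_test <- function(x, y, statistic = function(x, y) mean(x) - mean(y),
                             n_perm = 1000, seed = 1) {
  if (length(x) == 0 || length(y) == 0)
    stop("invalid argument: empty input", call. = FALSE)
  if (n_perm < 1) stop("invalid argument: n_perm must be >= 1", call. = FALSE)
  obs <- statistic(x, y)
  pool <- c(x, y)
  nx <- length(x); n <- length(pool)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, nx)
      abs(statistic(pool[idx], pool[-idx])) >= abs(obs)
    }, logical(1)))
  })
  list(statistic = obs, p = (1 + exceed) / (1 + n_perm))
}
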