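#' STR mutation parameters
#'
#' @param mu_s Per-generation probability that the repeat count mutates
#'   (stepwise model: a mutation changes the count by +1 or -1 with equal
#'   probability).
#' @param Ne Effective (diploid) population size; also fixes the time unit
#'   used on genealogies: branch times `t` are expressed in units of `Ne`
#'   generations, so a pair of lineages coalesces after `2 Ne` generations
#'   on average (`t = 2`).
#' @return A list of class `mutation_params`.
#' @export
mutation_params <- function(mu_s, Ne = 10400) {
  if (mu_s < 0 || mu_s > 1) stop("mu_s must lie in [0, 1]")
  if (Ne <= 0) stop("Ne must be positive")
  structure(list(mu_s = mu_s, Ne = Ne), class = "mutation_params")
}

#' Brownian-approximation transition potential of the stepwise model
#'
#' Over `g` generations the stepwise model's displacement has mean 0 and
#' variance `mu_s * g`; the Brownian approximation replaces the discrete
#' displacement law with a normal density of matching variance, clipped at
#' one so the value can serve directly as a potential:
#' \deqn{P(n_u | n_v, t) = \min\{1, N(n_u; n_v, Ne \mu_s t)\}.}
#' With `t` in `Ne`-generation units the variance `Ne * mu_s * t` equals
#' `mu_s * g` exactly.
#'
#' @param n_u Child repeat number(s).
#' @param n_v Parent repeat number(s).
#' @param t Branch time in `Ne`-generation units (non-negative).
#' @param params A [mutation_params()].
#' @return Potential value(s) in `[0, 1]`; at `t = 0` the identity
#'   indicator.
#' @export
transition_prob <- function(n_u, n_v, t, params) {
  if (any(t < 0)) stop("branch time t must be non-negative")
  v <- params$Ne * params$mu_s * t
  if (length(v) == 1L) v <- rep(v, length.out = max(length(n_u), length(n_v)))
  out <- ifelse(v == 0, as.numeric(n_u == n_v),
                pmin(1, stats::dnorm(n_u, mean = n_v, sd = sqrt(v))))
  as.numeric(out)
}

#' Cache of transition matrices over the repeat-state grid
#'
#' Builds the `(n_max - n_min + 1)` square matrix of
#' [transition_prob()] values, `entry[child, parent]`, for a branch time
#' `t`.  A small environment-backed cache reuses matrices across branch
#' lengths equal within `1e-12` (keyed on the variance).
#'
#' @inheritParams transition_prob
#' @param n_min,n_max Repeat-state grid bounds.
#' @param cache Optional environment from [transition_cache()].
#' @return Matrix of class `transition_matrix` with attribute `t`.
#' @export
build_transition_matrix <- function(t, params, n_min, n_max, cache = NULL) {
  stopifnot(n_min <= n_max, t >= 0)
  v <- params$Ne * params$mu_s * t
  key <- sprintf("%.12e", v)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  n_seq <- n_min:n_max
  d <- abs(outer(n_seq, n_seq, "-"))
  if (v == 0) {
    M <- (d == 0) * 1
  } else {
    M <- pmin(exp(-d^2 / (2 * v)) / sqrt(2 * pi * v), 1)
  }
  dimnames(M) <- list(child = n_seq, parent = n_seq)
  M <- structure(M, t = t, class = c("transition_matrix", "matrix"))
  if (!is.null(cache)) cache[[key]] <- M
  M
}

#' @rdname build_transition_matrix
#' @export
transition_cache <- function() new.env(parent = emptyenv())

#' Simulate stepwise repeat evolution over discrete generations
#'
#' Each generation the repeat count mutates with probability `mu_s`,
#' moving +1 or -1 with equal probability.  The walk is reflected at
#' `floor` (default 1): a step that would go below the floor is bounced
#' back, since a locus with zero copies would cease to exist as a repeat.
#'
#' @param n0 Starting repeat count.
#' @param generations Number of generations (non-negative integer).
#' @param mu_s Per-generation mutation probability.
#' @param floor Reflecting lower boundary.
#' @return The repeat count after `generations` generations.
#' @export
stepwise_simulate <- function(n0, generations, mu_s, floor = 1L) {
  stopifnot(generations >= 0, mu_s >= 0, mu_s <= 1)
  m <- stats::rbinom(1L, size = as.integer(generations), prob = mu_s)
  if (m == 0L) return(as.integer(n0))
  steps <- sample(c(-1L, 1L), m, replace = TRUE)
  if (n0 - m >= floor) return(as.integer(n0 + sum(steps)))  # reflection unreachable
  n <- as.integer(n0)
  for (st in steps) {
    n <- n + st
    if (n < floor) n <- 2L * floor - n
  }
  n
}
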