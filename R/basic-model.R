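#' Per-individual insert-size likelihood ("basic model")
#'
#' A spanning read pair with forward-read start `s` and reverse-read end `e`
#' yields an inferred insert size `l = e - s`.  If the sampled haplotype
#' carries `n` repeat units at a locus whose reference copy number is `n_r`
#' (unit length `u`), the fragment's true length is `l + u*(n - n_r)`, so
#' the likelihood of `l` given `n` is the insert-size pmf evaluated at the
#' shifted length, normalized over the lengths a spanning fragment starting
#' at `s` could have produced:
#' \deqn{P(l | n) = F(l + u(n - n_r)) / N(s, n)}
#' for `e_m - s < l <= K - u(n - n_r)`, else 0, with
#' \deqn{N(s, n) = \sum_{l = e_m - s + 1}^{K - u(n - n_r)} F(l + u(n - n_r)).}
#'
#' @name basic_model
NULL

# F(l + u*(n - n_r)) with out-of-range lengths mapping to 0
.shifted_pmf <- function(F, l, n, region) {
  insert_pmf(F, l + region$u * (n - region$n_r))
}

#' Naive normalization factor N(s, n)
#'
#' Direct summation oracle for the normalization factor; quadratic-time
#' reference for [build_normalization_table()].
#'
#' @param s Forward-read start position (1-based), must be `< s_m`.
#' @param n Candidate repeat number.
#' @param region An [str_region()].
#' @param F An [insert_dist()].
#' @return The normalization factor (0 when the summation range is empty).
#' @export
normalization_naive <- function(s, n, region, F) {
  K <- attr(F, "K")
  lo <- region$e_m - s + 1
  hi <- K - region$u * (n - region$n_r)
  if (lo > hi) return(0)
  sum(.shifted_pmf(F, lo:hi, n, region))
}

#' Build the normalization table N(s, n) by recurrence
#'
#' Fills the table for `s` in `[s_m - K, s_m - 1]` and `n` in
#' `[n_min, n_max]` using the two recurrences
#' `N(s+1, n) = N(s, n) + F(e_m - s + u(n - n_r))` and
#' `N(s, n+1) = N(s, n) - sum_{l = e_m-s+1}^{e_m-s+u} F(l + u(n - n_r))`,
#' i.e. O((n_max - n_min + 1) K) work instead of the naive O(K^2) per
#' repeat-number column.
#'
#' @inheritParams normalization_naive
#' @param n_min,n_max Repeat-number grid bounds.
#' @return A `norm_table`: numeric matrix with rows indexed by `s`
#'   (`s_m - K .. s_m - 1`) and columns by `n` (`n_min .. n_max`), plus
#'   attributes `s_range` and `n_range`.
#' @export
build_normalization_table <- function(region, F, n_min, n_max) {
  stopifnot(n_min <= n_max)
  K <- attr(F, "K")
  s_seq <- (region$s_m - K):(region$s_m - 1L)
  n_seq <- n_min:n_max
  tab <- matrix(0, nrow = length(s_seq), ncol = length(n_seq),
                dimnames = list(NULL, as.character(n_seq)))
  # cumulative sum of F for the O(u) window subtractions in the n-recurrence
  pmf <- unclass(F)
  cumF <- c(0, cumsum(pmf))                      # cumF[m + 1] = sum F(1..m)
  sumF <- function(a, b) {                       # sum_{m=a..b} F(m), clamped
    a <- pmax(a, 1L); b <- pmin(b, K)
    out <- numeric(length(a))
    ok <- a <= b
    out[ok] <- cumF[b[ok] + 1L] - cumF[a[ok]]
    out
  }
  u <- region$u; e_m <- region$e_m
  # first column (n = n_min): seed naively at s = s_m - K, then the
  # s-recurrence N(s+1, n) = N(s, n) + F(e_m - s + u*(n - n_r))
  tab[1L, 1L] <- normalization_naive(s_seq[1L], n_min, region, F)
  if (length(s_seq) > 1L) {
    add <- insert_pmf(F, e_m - s_seq[-length(s_seq)] + u * (n_min - region$n_r))
    tab[, 1L] <- tab[1L, 1L] + c(0, cumsum(add))
  }
  # remaining columns by the n-recurrence, vectorized over s
  if (length(n_seq) > 1L) {
    for (j in 2L:length(n_seq)) {
      n_prev <- n_seq[j - 1L]
      d <- u * (n_prev - region$n_r)
      lo <- e_m - s_seq + 1L + d
      tab[, j] <- tab[, j - 1L] - sumF(lo, lo + u - 1L)
    }
  }
  # the n-recurrence subtracts nearly equal sums where the true value is 0,
  # leaving +/-1e-17 residues; treat anything below 1e-12 as exact zero
  # (genuine normalization masses are bounded below by the smallest pmf entry)
  tab[abs(tab) < 1e-12] <- 0
  structure(tab, s_range = range(s_seq), n_range = c(n_min, n_max),
            class = "norm_table")
}

# table lookup with range checks; s and n may be vectors of equal length
.norm_lookup <- function(table, s, n) {
  sr <- attr(table, "s_range"); nr <- attr(table, "n_range")
  if (any(s < sr[1] | s > sr[2])) stop("position s outside normalization table range")
  if (any(n < nr[1] | n > nr[2])) stop("repeat number n outside normalization table range")
  unclass(table)[cbind(s - sr[1] + 1L, n - nr[1] + 1L)]
}

#' Likelihood P(l | n) of an inferred insert size
#'
#' @param l Inferred insert size (`e - s`), bp.
#' @param s Forward-read start position; must be strictly before the region
#'   start `s_m`.
#' @param n Candidate repeat number.
#' @inheritParams normalization_naive
#' @param table Optional precomputed [build_normalization_table()]; when
#'   `NULL` the factor is computed naively.
#' @return The probability, in `[0, 1]`.
#' @export
insert_likelihood <- function(l, s, n, region, F, table = NULL) {
  if (any(s >= region$s_m)) {
    stop("invalid observation: forward-read start must lie before the STR region")
  }
  K <- attr(F, "K")
  num <- .shifted_pmf(F, l, n, region)
  valid <- (l > region$e_m - s) & (l <= K - region$u * (n - region$n_r))
  num[!valid] <- 0
  N <- if (is.null(table)) {
    mapply(normalization_naive, s, n, MoreArgs = list(region = region, F = F))
  } else {
    .norm_lookup(table, s, n)
  }
  out <- numeric(length(num))
  pos <- num > 0
  if (any(pos & N <= 0)) {
    stop("inconsistency: zero normalization factor with nonzero numerator")
  }
  out[pos] <- num[pos] / N[pos]
  out
}

# D x (state count) matrix of P(l_d | n) across the repeat grid; rows are
# observations, columns the grid n_min..n_max.  Core of all grid searches.
.obs_lik_matrix <- function(obs, region, F, table) {
  nr <- attr(table, "n_range")
  n_seq <- nr[1]:nr[2]
  out <- matrix(0, nrow = nrow(obs), ncol = length(n_seq))
  for (j in seq_along(n_seq)) {
    out[, j] <- insert_likelihood(obs$l, obs$s, rep(n_seq[j], nrow(obs)),
                                  region, F, table)
  }
  out
}

# normalize an observation data.frame: accepts columns (s, e) and/or l
.as_obs <- function(obs) {
  obs <- as.data.frame(obs)
  if (is.null(obs$l)) {
    if (is.null(obs$s) || is.null(obs$e)) stop("observations need columns s,e or s,l")
    obs$l <- obs$e - obs$s
  }
  if (is.null(obs$s)) stop("observations need a column s")
  if (nrow(obs) > 0 && any(obs$l <= 0)) stop("insert sizes must be positive")
  obs
}

#' Diploid log-likelihood of spanning-pair observations
#'
#' Each read pair originates from one of the individual's two haplotypes
#' with equal probability, so the per-pair likelihood is the equal mixture
#' `(P(l|n1) + P(l|n2)) / 2`; observations multiply.
#'
#' @param obs Data frame of observations with columns `s` and `e` (or `s`
#'   and `l`).
#' @param n1,n2 Candidate repeat numbers for the two haplotypes.
#' @inheritParams insert_likelihood
#' @param floor Per-observation probability floor applied before taking
#'   logs, so an isolated impossible observation does not collapse the
#'   whole grid to `-Inf`.
#' @return The log-likelihood (0 for an empty observation set, with a
#'   warning).
#' @export
diploid_likelihood <- function(obs, n1, n2, region, F, table = NULL,
                               floor = 1e-300) {
  obs <- .as_obs(obs)
  if (nrow(obs) == 0L) {
    warning("no spanning-pair observations; log-likelihood is 0")
    return(0)
  }
  p1 <- insert_likelihood(obs$l, obs$s, rep(n1, nrow(obs)), region, F, table)
  p2 <- insert_likelihood(obs$l, obs$s, rep(n2, nrow(obs)), region, F, table)
  sum(log(pmax((p1 + p2) / 2, floor)))
}

#' Diploid repeat-number estimation by grid search
#'
#' Maximizes [diploid_likelihood()] over the full
#' `(n_max - n_min + 1)^2` grid.  Ties are broken by preferring the pair
#' closest to the reference (`|n1 - n_r| + |n2 - n_r|`), then
#' lexicographically; the returned call is canonicalized to `n1 <= n2`.
#'
#' @inheritParams diploid_likelihood
#' @param n_min,n_max Grid bounds.
#' @param table Optional precomputed normalization table covering
#'   `[n_min, n_max]` (built if `NULL`).
#' @return A list of class `diploid_call`: `n1`, `n2` (`n1 <= n2`) and
#'   `loglik`.
#' @export
basic_model_estimate <- function(obs, region, F, n_min = 0L, n_max = 40L,
                                 table = NULL) {
  stopifnot(n_min <= n_max)
  obs <- .as_obs(obs)
  if (nrow(obs) == 0L) stop("no spanning pairs: cannot estimate repeat numbers")
  if (is.null(table)) table <- build_normalization_table(region, F, n_min, n_max)
  n_seq <- n_min:n_max
  P <- .obs_lik_matrix(obs, region, F, table)     # D x S
  S <- length(n_seq)
  ll <- matrix(NA_real_, S, S)
  for (a in seq_len(S)) {
    mix <- (P[, a] + P) / 2                       # D x S, column b = (n_a, n_b)
    ll[a, ] <- colSums(log(pmax(mix, 1e-300)))
  }
  best <- max(ll)
  idx <- which(ll >= best - 0, arr.ind = TRUE)
  idx <- idx[ll[idx] == best, , drop = FALSE]
  n1c <- n_seq[idx[, 1]]; n2c <- n_seq[idx[, 2]]
  pref <- abs(n1c - region$n_r) + abs(n2c - region$n_r)
  ord <- order(pref, n1c, n2c)
  n1 <- n1c[ord[1]]; n2 <- n2c[ord[1]]
  structure(list(n1 = min(n1, n2), n2 = max(n1, n2), loglik = best),
            class = "diploid_call")
}

#' @export
print.diploid_call <- function(x, ...) {
  cat(sprintf("diploid call: (%d, %d), log-likelihood %.4f\n",
              x$n1, x$n2, x$loglik))
  invisible(x)
}
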