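# Shared fixtures: tiny analytic toy instances and random-instance builders.

# toy locus: 10 bp region of 2 bp units, reference 5 copies
toy_region <- function() {
  suppressWarnings(str_region("chrT", 100L, 109L, unit = 2L, ref_repeat = 5L,
                              id = "toy"))
}

# uniform 0.1 mass on lengths 10..19, cap 19
toy_uniform_F <- function() {
  insert_dist(stats::setNames(rep(0.1, 10), 10:19), K = 19L)
}

# peaked pmf on 14..18, cap 18
toy_peaked_F <- function() {
  insert_dist(stats::setNames(c(0.1, 0.2, 0.4, 0.2, 0.1), 14:18), K = 18L)
}

# random pmf supported on a random sub-range of 1..K
random_insert_dist <- function(K = 60L) {
  lo <- sample.int(K - 10L, 1L)
  hi <- min(K, lo + sample.int(30L, 1L))
  p <- stats::runif(hi - lo + 1L)
  insert_dist(stats::setNames(p / sum(p), lo:hi), K = K)
}

# random small region compatible with K-scale toys
random_region <- function() {
  u <- sample(1:4, 1L)
  n_r <- sample(3:8, 1L)
  s_m <- 100L
  suppressWarnings(str_region("chrT", s_m, s_m + u * n_r - 1L,
                              unit = u, ref_repeat = n_r))
}

# random ultrametric tree over I individuals with paired leaf labels
random_pair_tree <- function(I) {
  simulate_coalescent_tree(2L * I)
}

# random positive factor list over a small state grid for I individuals
random_factors <- function(I, n_min, n_max, peaked = FALSE) {
  S <- n_max - n_min + 1L
  out <- lapply(seq_len(I), function(i) {
    m <- matrix(stats::runif(S * S), S, S)
    m <- (m + t(m)) / 2                      # diploid factors are symmetric
    if (peaked) m <- m^8                     # sharpen (still symmetric)
    attr(m, "n_range") <- c(n_min, n_max)
    m
  })
  names(out) <- sprintf("s%03d", seq_len(I))
  out
}

expect_message_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
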