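# Multi-tree belief propagation: message updates, engines, decoding,
# exact oracles.

# two-leaf, one-individual tree with controllable branch variance:
# variance = Ne * mu_s * t with Ne = 1, mu_s = 1 -> variance = t
pair_tree <- function(t = 1) {
  coalescent_tree(parent = c(3L, 3L, NA), children = matrix(1:2, 2, 1),
                  time = c(0, 0, t), labels = c("s001_1", "s001_2"))
}
unit_params <- function() mutation_params(1, 1)

test_that("diploid factor: empty-obs table, symmetry, toy proportions", {
  reg <- toy_region()
  F <- toy_uniform_F()
  f0 <- build_diploid_factor(data.frame(s = integer(0), l = integer(0)),
                             reg, F, 0L, 10L)
  expect_true(all(f0 == 1))
  f <- build_diploid_factor(data.frame(s = 95, l = 15), reg, F, 0L, 10L)
  expect_equal(unclass(f), t(unclass(f)), ignore_attr = TRUE)
  # entries proportional to the per-observation mixture likelihood:
  # f(5,6)/f(5,5) = 0.26667 / 0.2
  expect_equal(f["5", "6"] / f["5", "5"], ((0.2 + 0.1 / 0.3) / 2) / 0.2,
               tolerance = 1e-9)
  expect_equal(max(f), 1)
})

test_that("leaf-to-parent update reproduces the normal-density row", {
  f <- random_factors(1, 4L, 6L)
  state <- init_bp_state(f, list(pair_tree(1)), unit_params(), 4L, 6L)
  state$m21[, 1] <- c(0, 1, 0)                  # point mass on state 5
  msg <- update_leaf_to_parent(state, 1, 1, mode = "sum")
  dens <- stats::dnorm(c(4, 5, 6), 5, 1)
  expect_message_equal(msg, dens / sum(dens))
  expect_equal(round(dens[1], 3), 0.242)
  # near-identity transitions propagate point masses unchanged
  state0 <- init_bp_state(f, list(pair_tree(1)), mutation_params(0, 1), 4L, 6L)
  state0$m21[, 1] <- c(0, 1, 0)
  expect_message_equal(update_leaf_to_parent(state0, 1, 1, mode = "sum"),
                       c(0, 1, 0), tol = 1e-140)
  # flat transitions (huge variance) give a uniform message
  statef <- init_bp_state(f, list(pair_tree(1e12)), unit_params(), 4L, 6L)
  statef$m21[, 1] <- c(0.1, 0.2, 0.7)
  expect_message_equal(update_leaf_to_parent(statef, 1, 1, mode = "sum"),
                       rep(1 / 3, 3), tol = 1e-6)
})

test_that("internal updates match a dense matrix-product oracle", {
  set.seed(501)
  I <- 2L
  tr <- random_pair_tree(I)
  params <- mutation_params(2e-3, 500)
  f <- random_factors(I, 0L, 4L)
  state <- init_bp_state(f, list(tr), params, 0L, 4L)
  # randomize incoming messages
  S <- 5L
  for (v in seq_len(2L * tr$n_leaf - 1L)) {
    state$up[[1]][, v] <- coalstr:::.renorm(stats::runif(S))
    state$down[[1]][, v] <- coalstr:::.renorm(stats::runif(S))
  }
  v <- 2L * tr$n_leaf - 1L                      # root is oldest internal node
  v <- which.max(state$trees[[1]]$tree$time)
  ch <- state$trees[[1]]$tree$children[, v - tr$n_leaf]
  # pick a non-root internal node for the upward check
  w <- setdiff((tr$n_leaf + 1L):(2L * tr$n_leaf - 1L), v)[1]
  Mw <- unclass(state$trees[[1]]$M[[w]])
  chw <- state$trees[[1]]$tree$children[, w - tr$n_leaf]
  inc <- state$up[[1]][, chw[1]] * state$up[[1]][, chw[2]]
  expect_message_equal(update_internal(state, 1, w, "up"),
                       as.numeric(t(Mw) %*% inc) / sum(t(Mw) %*% inc),
                       tol = 1e-12)
  # downward from the root uses a flat parent message
  Mc <- unclass(state$trees[[1]]$M[[ch[1]]])
  inc2 <- rep(1, S) * state$up[[1]][, ch[2]]
  expect_message_equal(update_internal(state, 1, v, "down", child = ch[1]),
                       as.numeric(Mc %*% inc2) / sum(Mc %*% inc2),
                       tol = 1e-12)
})

test_that("cross-haplotype update matches exhaustive sum and max oracles", {
  set.seed(502)
  I <- 2L
  ens <- list(random_pair_tree(I), random_pair_tree(I))
  params <- mutation_params(1e-3, 1000)
  f <- random_factors(I, 0L, 2L)
  state <- init_bp_state(f, ens, params, 0L, 2L)
  for (g in 1:2) {
    nn <- ncol(state$down[[g]])
    state$down[[g]][] <- apply(matrix(stats::runif(3 * nn), 3), 2,
                               coalstr:::.renorm)
  }
  state <- coalstr:::.bp_aggregate(state)
  i <- 2L
  for (mode in c("sum", "max")) {
    upd <- update_cross_haplotype(state, i, mode)
    m12_oracle <- numeric(3)
    for (n2 in 1:3) {
      terms <- vapply(1:3, function(n1) f[[i]][n1, n2] * state$T1[n1, i],
                      numeric(1))
      m12_oracle[n2] <- if (mode == "sum") sum(terms) else max(terms)
    }
    expect_message_equal(upd$m12, m12_oracle / sum(m12_oracle), tol = 1e-12)
  }
  # a factor with a single surviving entry (a, b) forwards a point mass on
  # b in both modes (asymmetric on purpose: the symmetrized version has two
  # entries and spreads the mass over both pair orderings)
  fpt <- f
  fpt[[1]][] <- 1e-300
  fpt[[1]][2, 3] <- 1
  st2 <- init_bp_state(fpt, ens, params, 0L, 2L)
  st2 <- coalstr:::.bp_aggregate(st2)
  for (mode in c("sum", "max")) {
    upd <- update_cross_haplotype(st2, 1L, mode)
    expect_equal(which.max(upd$m12), 3L)
    expect_gt(max(upd$m12), 1 - 1e-9)
  }
})

test_that("compiled and reference engines agree on random instances", {
  set.seed(503)
  for (k in 1:6) {
    I <- sample(1:3, 1)
    G <- sample(1:3, 1)
    ens <- replicate(G, random_pair_tree(I), simplify = FALSE)
    params <- mutation_params(10^stats::runif(1, -4, -2), 10400)
    f <- random_factors(I, 0L, sample(3:6, 1), peaked = (k %% 2 == 0))
    nr <- attr(f[[1]], "n_range")
    a <- bp_infer(f, ens, params, nr[1], nr[2], 10L, 10L, engine = "cpp")
    b <- bp_infer(f, ens, params, nr[1], nr[2], 10L, 10L, engine = "r")
    expect_message_equal(a$m12, b$m12, tol = 1e-9)
    expect_message_equal(a$m21, b$m21, tol = 1e-9)
    expect_message_equal(a$agg1, b$agg1, tol = 1e-9)
    expect_message_equal(a$agg2, b$agg2, tol = 1e-9)
  }
})

test_that("BP is deterministic across repeated runs", {
  set.seed(504)
  I <- 2L
  ens <- replicate(2, random_pair_tree(I), simplify = FALSE)
  f <- random_factors(I, 0L, 5L)
  params <- mutation_params(1e-3, 10400)
  a <- bp_infer(f, ens, params, 0L, 5L)
  b <- bp_infer(f, ens, params, 0L, 5L)
  expect_identical(a$m12, b$m12)
  expect_identical(a$agg1, b$agg1)
})

# exact leaf marginals of the tree-only model by full enumeration over all
# node states (root uniform / unweighted)
enum_leaf_marginals <- function(tr, params, n_min, n_max) {
  n_seq <- n_min:n_max
  S <- length(n_seq)
  n_nodes <- 2L * tr$n_leaf - 1L
  cache <- transition_cache()
  bt <- coalstr:::branch_times(tr)
  M <- lapply(seq_len(n_nodes), function(v) {
    if (is.na(tr$parent[v])) return(NULL)
    unclass(build_transition_matrix(bt[v], params, n_min, n_max, cache))
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n_nodes)))
  w <- apply(grid, 1, function(cfg) {
    prod(vapply(seq_len(n_nodes), function(v) {
      if (is.na(tr$parent[v])) 1 else M[[v]][cfg[v], cfg[tr$parent[v]]]
    }, numeric(1)))
  })
  marg <- matrix(0, S, tr$n_leaf)
  for (v in seq_len(tr$n_leaf)) {
    for (s in seq_len(S)) marg[s, v] <- sum(w[grid[, v] == s])
  }
  sweep(marg, 2, colSums(marg), "/")
}

test_that("with uniform factors loopy BP equals exact tree marginals", {
  set.seed(505)
  for (k in 1:5) {
    I <- 2L
    tr <- random_pair_tree(I)
    params <- mutation_params(10^stats::runif(1, -3.5, -2.5), 10400)
    n_min <- 0L; n_max <- 2L
    f <- lapply(1:I, function(i) matrix(1, 3, 3))
    names(f) <- sprintf("s%03d", 1:I)
    res <- bp_infer(f, list(tr), params, n_min, n_max, 10L, 0L, engine = "r")
    exact <- enum_leaf_marginals(tr, params, n_min, n_max)
    lab_col <- match(paste0(names(f), "_1"), tr$labels)
    for (i in seq_len(I)) {
      # belief at leaf i_1 = cross message (uniform) x tree aggregate
      expect_message_equal(res$agg1[, i], exact[, lab_col[i]], tol = 1e-9)
    }
  }
})

test_that("decode matches the marginal-MAP oracle at weak coupling", {
  # weak transition coupling (branch variance >> 1 state) with peaked
  # factors is the regime where loopy BP decoding is reliable; comparison
  # is up to per-individual haplotype swaps (the diploid factor is
  # label-symmetric, so (a, b) and (b, a) are the same call)
  canon <- function(df) t(apply(cbind(df$n1, df$n2), 1, sort))
  set.seed(611)
  for (k in 1:25) {
    I <- sample(1:3, 1)
    G <- sample(1:3, 1)
    n_max <- sample(2:4, 1)
    ens <- replicate(G, random_pair_tree(I), simplify = FALSE)
    params <- mutation_params(10^stats::runif(1, -3, -2.5), 10400)
    f <- random_factors(I, 0L, n_max, peaked = TRUE)
    res <- bp_infer(f, ens, params, 0L, n_max, 10L, 10L)
    calls <- decode(res, n_r = 0L, factors = f)
    oracle <- brute_force_marginal_map(f, ens, params, 0L, n_max)
    expect_equal(canon(calls), canon(oracle$calls))
  }
})

test_that("brute force respects scale invariance and the flat-tree case", {
  set.seed(507)
  I <- 2L
  ens <- list(random_pair_tree(I))
  params <- mutation_params(1e-3, 10400)
  f <- random_factors(I, 0L, 3L, peaked = TRUE)
  o1 <- brute_force_marginal_map(f, ens, params, 0L, 3L)
  f2 <- f
  f2[[1]] <- f2[[1]] * 7.3
  o2 <- brute_force_marginal_map(f2, ens, params, 0L, 3L)
  expect_equal(o1$calls, o2$calls)
  expect_equal(o2$objective, 7.3 * o1$objective, tolerance = 1e-9)
})

test_that("decode scale invariance and uniform tie-break to the reference", {
  set.seed(508)
  I <- 2L
  ens <- list(random_pair_tree(I), random_pair_tree(I))
  params <- mutation_params(1e-3, 10400)
  f <- random_factors(I, 0L, 5L, peaked = TRUE)
  r1 <- bp_infer(f, ens, params, 0L, 5L)
  f2 <- f
  f2[[2]] <- f2[[2]] * 123
  r2 <- bp_infer(f2, ens, params, 0L, 5L)
  expect_equal(decode(r1, n_r = 3L, factors = f),
               decode(r2, n_r = 3L, factors = f2))
  # fully uniform beliefs decode to the reference pair
  fu <- lapply(f, function(m) matrix(1, 6, 6))
  names(fu) <- names(f)
  ru <- bp_infer(fu, list(random_pair_tree(I)), mutation_params(1, 1),
                 0L, 5L, 0L, 0L)
  cu <- decode(ru, n_r = 4L, factors = fu)
  expect_true(all(cu$n1 == 4L & cu$n2 == 4L))
})

test_that("estimate_repeats reduces to the basic model for one individual", {
  set.seed(509)
  reg <- toy_region()
  K <- 400L
  F <- normal_insert_dist(200, 15, K = K)
  truth <- matrix(c(4L, 6L), 1, 2, dimnames = list("s001", NULL))
  obs <- simulate_observations(truth, reg, 25, read_len = 50,
                               insert_mean = 200, insert_sd = 15, K = K)
  flat_tree <- pair_tree(1e12)       # enormous branch -> flat transitions
  est <- estimate_repeats(obs, list(flat_tree), reg, F, unit_params(),
                          0L, 10L)
  basic <- basic_model_estimate(obs[["s001"]], reg, F, 0L, 10L)
  expect_equal(sort(c(est$calls$n1, est$calls$n2)), c(basic$n1, basic$n2))
})

test_that("a read-less individual inherits its clade's repeat state", {
  # three individuals on one short-branched tree; s003 has no reads
  labs <- paste0(rep(sprintf("s%03d", 1:3), each = 2), "_", 1:2)
  parent <- c(7L, 7L, 8L, 8L, 9L, 9L, 10L, 10L, 11L, 11L, NA)
  children <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L), 2, 5)
  time <- c(rep(0, 6), 1e-4, 2e-4, 3e-4, 4e-4, 5e-4)
  tr <- coalescent_tree(parent, children, time, labs)
  params <- mutation_params(1e-6, 10400)   # near-identity transitions
  S <- 5L
  f_point <- matrix(1e-300, S, S); f_point[3, 3] <- 1
  f <- list(s001 = f_point, s002 = f_point,
            s003 = matrix(1, S, S))
  res <- bp_infer(f, list(tr), params, 0L, 4L)
  calls <- decode(res, n_r = 0L, factors = f)
  expect_equal(calls$n1[calls$sample == "s003"], 2L)
  expect_equal(calls$n2[calls$sample == "s003"], 2L)
  oracle <- brute_force_marginal_map(f, list(tr), params, 0L, 4L)
  expect_equal(calls$n1, oracle$calls$n1)
  expect_equal(calls$n2, oracle$calls$n2)
})

test_that("permuting the observation list leaves calls unchanged", {
  set.seed(510)
  reg <- toy_region()
  K <- 400L
  F <- normal_insert_dist(200, 15, K = K)
  truth <- matrix(c(4L, 5L, 6L, 6L, 5L, 4L), 3, 2,
                  dimnames = list(sprintf("s%03d", 1:3), NULL))
  obs <- simulate_observations(truth, reg, 20, read_len = 50,
                               insert_mean = 200, insert_sd = 15, K = K)
  ens <- list(random_pair_tree(3))
  params <- mutation_params(1e-3, 10400)
  a <- estimate_repeats(obs, ens, reg, F, params, 0L, 10L)
  b <- estimate_repeats(obs[c(3, 1, 2)], ens, reg, F, params, 0L, 10L)
  expect_equal(a$calls, b$calls)
})

test_that("sample/leaf mismatches raise informative errors", {
  reg <- toy_region()
  F <- toy_uniform_F()
  obs <- list(sXXX = data.frame(s = 95, l = 15))
  expect_error(
    estimate_repeats(obs, list(random_pair_tree(2)), reg, F,
                     mutation_params(1e-3), 0L, 10L),
    "sXXX")
})
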