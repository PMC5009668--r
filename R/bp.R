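#' Multi-tree belief propagation for joint repeat-number estimation
#'
#' The joint model couples, per individual, the diploid insert-size factor
#' of the basic model with every genealogy in a sampled tree ensemble;
#' branches carry the Brownian-approximation stepwise transition potential.
#' Decoding the per-haplotype repeat numbers is a marginal MAP problem
#' (internal-node repeats and trees are summed out, leaf repeats
#' maximized), approximated by ten cycles of loopy (sum-product) belief
#' propagation followed by ten cycles of mixed-product belief propagation
#' initialized from the loopy messages.
#'
#' The fixed message schedule for one cycle is: cross-haplotype messages
#' for all individuals (in sample order), then per tree (in ensemble
#' order) an upward sweep leaves-to-root, then a downward sweep
#' root-to-leaves.  Every message is renormalized to sum one.
#'
#' @name multi_tree_bp
NULL

#' Build the diploid insert-size factor table for one individual
#'
#' `table[n1, n2] = exp(loglik(n1, n2) - max loglik)`, i.e. the diploid
#' likelihood surface rescaled so its maximum is one (the scale is
#' irrelevant to decoding and is dropped).  An individual without spanning
#' pairs contributes no information and receives the all-ones table.
#'
#' @inheritParams diploid_likelihood
#' @param n_min,n_max Repeat-state grid bounds.
#' @param table Optional precomputed normalization table.
#' @return An `S x S` symmetric matrix over the repeat grid, with
#'   attribute `n_range`.
#' @export
build_diploid_factor <- function(obs, region, F, n_min = 0L, n_max = 40L,
                                 table = NULL) {
  n_seq <- n_min:n_max
  S <- length(n_seq)
  obs <- .as_obs(obs)
  if (nrow(obs) == 0L) {
    out <- matrix(1, S, S)
  } else {
    if (is.null(table)) table <- build_normalization_table(region, F, n_min, n_max)
    P <- .obs_lik_matrix(obs, region, F, table)
    ll <- matrix(NA_real_, S, S)
    for (a in seq_len(S)) {
      ll[a, ] <- colSums(log(pmax((P[, a] + P) / 2, 1e-300)))
    }
    out <- exp(ll - max(ll))
    out <- pmax(out, 1e-300)
  }
  dimnames(out) <- list(n_seq, n_seq)
  attr(out, "n_range") <- c(n_min, n_max)
  out
}

# --- BP state -------------------------------------------------------------

# Internal layout of a bp_state:
#   S, n_seq            repeat-state grid
#   samples             individual labels, in order
#   factors             list of S x S matrices (one per individual)
#   trees               list of per-tree specs: tree, leaf_indiv, leaf_hap,
#                       postorder, M (list of transition matrices per node)
#   up, down            per tree: S x n_nodes message matrices
#   m12, m21, T1, T2    S x I matrices (cross messages, tree aggregates)
#   mode                "sum" or "max" (current cross-update semiring)

#' Initialize a belief-propagation state
#'
#' @param factors Named list (by sample) of diploid factor tables from
#'   [build_diploid_factor()].
#' @param ensemble List of [coalescent_tree()]s whose leaf labels are
#'   `"<sample>_1"` / `"<sample>_2"` over exactly the factor samples.
#' @param params A [mutation_params()].
#' @param n_min,n_max Repeat-state grid bounds.
#' @return A `bp_state` list; all messages start uniform.
#' @export
init_bp_state <- function(factors, ensemble, params, n_min = 0L, n_max = 40L) {
  samples <- names(factors)
  if (is.null(samples)) stop("factors must be a named list (sample ids)")
  S <- n_max - n_min + 1L
  want <- sort(paste0(rep(samples, each = 2L), "_", c(1L, 2L)))
  cache <- transition_cache()
  trees <- lapply(ensemble, function(tr) {
    if (!setequal(tr$labels, want)) {
      stop("tree leaves do not match the sample set; unmatched: ",
           paste(union(setdiff(tr$labels, want), setdiff(want, tr$labels)),
                 collapse = ", "))
    }
    sample_of <- sub("_[12]$", "", tr$labels)
    hap_of <- as.integer(sub("^.*_", "", tr$labels))
    bt <- branch_times(tr)
    M <- vector("list", 2L * tr$n_leaf - 1L)
    for (v in seq_along(M)) {
      if (!is.na(tr$parent[v])) {
        M[[v]] <- build_transition_matrix(bt[v], params, n_min, n_max, cache)
      }
    }
    list(tree = tr,
         leaf_indiv = match(sample_of, samples),
         leaf_hap = hap_of,
         postorder = .postorder(tr),
         variance = ifelse(is.na(bt), 0, params$Ne * params$mu_s * bt),
         M = M)
  })
  unif <- 1 / S
  state <- list(
    S = S, n_seq = n_min:n_max, samples = samples, factors = factors,
    params = params, trees = trees,
    up = lapply(trees, function(ts) matrix(unif, S, 2L * ts$tree$n_leaf - 1L)),
    down = lapply(trees, function(ts) matrix(unif, S, 2L * ts$tree$n_leaf - 1L)),
    m12 = matrix(unif, S, length(samples)),
    m21 = matrix(unif, S, length(samples)),
    T1 = matrix(unif, S, length(samples)),
    T2 = matrix(unif, S, length(samples)),
    mode = "sum")
  class(state) <- "bp_state"
  state
}

# normalize to sum one, flooring entries at 1e-150 so products of
# point-mass-like messages on near-identity branches cannot underflow to
# an exact zero vector (matches the compiled engine)
.renorm <- function(v, what = "message") {
  s <- sum(v)
  if (!is.finite(s) || s <= 0) stop("non-finite or all-zero ", what)
  pmax(v / s, 1e-150)
}

# recompute tree-aggregate messages T1/T2 from current downward messages
.bp_aggregate <- function(state) {
  I <- length(state$samples)
  T1 <- matrix(0, state$S, I); T2 <- matrix(0, state$S, I)
  for (g in seq_along(state$trees)) {
    ts <- state$trees[[g]]
    for (v in seq_len(ts$tree$n_leaf)) {
      i <- ts$leaf_indiv[v]
      if (ts$leaf_hap[v] == 1L) T1[, i] <- T1[, i] + state$down[[g]][, v]
      else T2[, i] <- T2[, i] + state$down[[g]][, v]
    }
  }
  state$T1 <- apply(T1, 2, .renorm, what = "tree-aggregate")
  state$T2 <- apply(T2, 2, .renorm, what = "tree-aggregate")
  state
}

#' Cross-haplotype message update (Eq.-6-style)
#'
#' Computes the message from haplotype 1 to haplotype 2 of individual `i`
#' (and symmetrically back): the diploid factor is combined with the
#' tree-aggregate message `T(n) = sum_g m_{parent(i1,g) -> i1}(n)` using
#' the sum semiring for loopy BP or the max semiring for mixed-product BP.
#'
#' @param state A `bp_state`.
#' @param i Individual index (into `state$samples`).
#' @param mode `"sum"` or `"max"`.
#' @return List with normalized messages `m12` and `m21`.
#' @export
update_cross_haplotype <- function(state, i, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  f <- state$factors[[i]]
  comb <- if (mode == "sum") {
    function(fm, T) as.numeric(crossprod(fm, T))    # sum_n1 f(n1, n2) T(n1)
  } else {
    function(fm, T) apply(fm * T, 2, max)           # max_n1 f(n1, n2) T(n1)
  }
  list(m12 = .renorm(comb(f, state$T1[, i]), "cross-haplotype message"),
       m21 = .renorm(comb(t(f), state$T2[, i]), "cross-haplotype message"))
}

#' Leaf-to-parent message update
#'
#' `m(n_p) = sum_{n} P(n | n_p, t) * m_cross(n)`, where `m_cross` is the
#' message from the individual's other haplotype.  In mixed-product mode
#' the sum is restricted to the argmax set of
#' `m_cross(n) * tree_aggregate(n)`.
#'
#' @param state A `bp_state`.
#' @param g Tree index.
#' @param leaf Leaf node id within tree `g`.
#' @param mode `"sum"` or `"max"` (mixed-product restriction).
#' @return The normalized upward message (length-S vector).
#' @export
update_leaf_to_parent <- function(state, g, leaf, mode = state$mode) {
  ts <- state$trees[[g]]
  i <- ts$leaf_indiv[leaf]
  cross <- if (ts$leaf_hap[leaf] == 1L) state$m21[, i] else state$m12[, i]
  if (mode == "max") {
    agg <- if (ts$leaf_hap[leaf] == 1L) state$T1[, i] else state$T2[, i]
    b <- cross * agg
    cross <- ifelse(b >= max(b) * (1 - 1e-12), cross, 0)
  }
  M <- ts$M[[leaf]]
  .renorm(as.numeric(crossprod(M, cross)), "leaf upward message")
}

#' Internal-node message updates
#'
#' Upward: `m_{v->p}(n_p) = sum_{n_v} P(n_v|n_p, t) m_{o1->v}(n_v)
#' m_{o2->v}(n_v)`.  Downward to child `o1`:
#' `m_{v->o1}(n) = sum_{n_v} P(n|n_v, t) m_{p->v}(n_v) m_{o2->v}(n_v)`,
#' with a flat parent message at the root.
#'
#' @param state A `bp_state`.
#' @param g Tree index.
#' @param v Internal node id.
#' @param direction `"up"` or `"down"`.
#' @param child For `"down"`, the child node id the message is sent to.
#' @return The normalized message.
#' @export
update_internal <- function(state, g, v, direction = c("up", "down"),
                            child = NULL) {
  direction <- match.arg(direction)
  ts <- state$trees[[g]]
  ch <- .tree_children(ts$tree, v)
  if (direction == "up") {
    inc <- state$up[[g]][, ch[1]] * state$up[[g]][, ch[2]]
    .renorm(as.numeric(crossprod(ts$M[[v]], inc)), "internal upward message")
  } else {
    if (is.null(child) || !child %in% ch) stop("'child' must be a child of v")
    sib <- ch[ch != child]
    par_msg <- if (v == ts$tree$root) rep(1, state$S) else state$down[[g]][, v]
    inc <- par_msg * state$up[[g]][, sib]
    .renorm(as.numeric(ts$M[[child]] %*% inc), "internal downward message")
  }
}

# one full cycle under the given semiring mode
.bp_cycle <- function(state, mode) {
  state <- .bp_aggregate(state)
  state$mode <- mode
  for (i in seq_along(state$samples)) {
    upd <- update_cross_haplotype(state, i, mode)
    state$m12[, i] <- upd$m12
    state$m21[, i] <- upd$m21
  }
  for (g in seq_along(state$trees)) {
    ts <- state$trees[[g]]
    for (v in ts$postorder) {
      if (v == ts$tree$root) next
      state$up[[g]][, v] <- if (v <= ts$tree$n_leaf) {
        update_leaf_to_parent(state, g, v, mode)
      } else {
        update_internal(state, g, v, "up")
      }
    }
  }
  for (g in seq_along(state$trees)) {
    ts <- state$trees[[g]]
    for (v in rev(ts$postorder)) {
      if (v <= ts$tree$n_leaf) next
      for (ch in .tree_children(ts$tree, v)) {
        state$down[[g]][, ch] <- update_internal(state, g, v, "down", child = ch)
      }
    }
  }
  state
}

#' Run loopy (sum-product) BP cycles
#'
#' @param state A `bp_state`.
#' @param cycles Number of full cycles.
#' @return The updated `bp_state`.
#' @export
run_loopy <- function(state, cycles = 10L) {
  for (k in seq_len(cycles)) state <- .bp_cycle(state, "sum")
  state
}

#' Run mixed-product BP cycles
#'
#' @inheritParams run_loopy
#' @export
run_mixed_product <- function(state, cycles = 10L) {
  for (k in seq_len(cycles)) state <- .bp_cycle(state, "max")
  state
}

#' Decode per-haplotype repeat numbers from a BP state
#'
#' The belief of haplotype 1 of individual `i` is
#' `m_{i2->i1}(n) * sum_g m_{parent -> i1}(n)` (and symmetrically for
#' haplotype 2).  After mixed-product cycles these two vectors are the two
#' max-marginals of the individual's pair belief
#' `B_i(n1, n2) = f_i(n1, n2) * T_1(n1) * T_2(n2)` (with `T_h` the
#' normalized tree aggregates), so taking their argmaxes independently can
#' return a jointly inconsistent -- even zero-probability -- pair whenever
#' the pair surface has near-ties (a label-symmetric factor always does).
#' The call is therefore the joint argmax of `B_i`, which realizes the
#' same per-haplotype argmaxes consistently; ties are broken toward the
#' reference (`|n1 - n_r| + |n2 - n_r|`), then lexicographically.
#'
#' @param state A `bp_state` (or the result list of the compiled engine,
#'   see [estimate_repeats()]).
#' @param n_r Reference repeat number used for tie-breaking.
#' @param factors Optional named list of diploid factor tables for the
#'   joint decoding; taken from a `bp_state` automatically.  Without
#'   factors the pair belief reduces to the product of tree aggregates.
#' @return A data frame of class `repeat_callset`: `sample`, `n1`, `n2`,
#'   `belief1`, `belief2` (normalized belief mass of the called state).
#' @export
decode <- function(state, n_r = 0L, factors = NULL) {
  if (inherits(state, "bp_state")) {
    if (is.null(factors)) factors <- state$factors
    state <- .bp_aggregate(state)
    res <- list(m12 = state$m12, m21 = state$m21,
                agg1 = state$T1, agg2 = state$T2)
    n_seq <- state$n_seq
    samples <- state$samples
  } else {
    res <- state
    n_seq <- attr(state, "n_seq")
    samples <- attr(state, "samples")
  }
  S <- length(n_seq)
  I <- length(samples)
  out <- data.frame(sample = samples, n1 = NA_integer_, n2 = NA_integer_,
                    belief1 = NA_real_, belief2 = NA_real_)
  for (i in seq_len(I)) {
    b1 <- res$m21[, i] * res$agg1[, i]; b1 <- b1 / sum(b1)
    b2 <- res$m12[, i] * res$agg2[, i]; b2 <- b2 / sum(b2)
    B <- outer(res$agg1[, i], res$agg2[, i])
    if (!is.null(factors)) B <- B * factors[[i]]
    tied <- which(B >= max(B) * (1 - 1e-12), arr.ind = TRUE)
    pref <- abs(n_seq[tied[, 1]] - n_r) + abs(n_seq[tied[, 2]] - n_r)
    k <- order(pref, n_seq[tied[, 1]], n_seq[tied[, 2]])[1]
    i1 <- tied[k, 1]; i2 <- tied[k, 2]
    out$n1[i] <- n_seq[i1]; out$belief1[i] <- b1[i1]
    out$n2[i] <- n_seq[i2]; out$belief2[i] <- b2[i2]
  }
  class(out) <- c("repeat_callset", "data.frame")
  out
}

# --- compiled engine ------------------------------------------------------

# per-tree spec lists for cpp_bp_run
.bp_cpp_spec <- function(factors, ensemble, params, n_min, n_max) {
  samples <- names(factors)
  want <- sort(paste0(rep(samples, each = 2L), "_", c(1L, 2L)))
  lapply(ensemble, function(tr) {
    if (!setequal(tr$labels, want)) {
      stop("tree leaves do not match the sample set; unmatched: ",
           paste(union(setdiff(tr$labels, want), setdiff(want, tr$labels)),
                 collapse = ", "))
    }
    bt <- branch_times(tr)
    list(n_leaf = tr$n_leaf,
         parent = tr$parent,
         children = tr$children,
         postorder = .postorder(tr),
         leaf_indiv = match(sub("_[12]$", "", tr$labels), samples) - 1L,
         leaf_hap = as.integer(sub("^.*_", "", tr$labels)) - 1L,
         variance = ifelse(is.na(bt), 0, params$Ne * params$mu_s * bt))
  })
}

# run the compiled BP engine; returns m12/m21/agg1/agg2 with metadata
.bp_cpp_run <- function(factors, ensemble, params, n_min, n_max,
                        loopy_cycles, mixed_cycles, raw_weights = FALSE) {
  spec <- .bp_cpp_spec(factors, ensemble, params, n_min, n_max)
  res <- cpp_bp_run(spec, unname(lapply(factors, unclass)),
                    n_max - n_min + 1L, loopy_cycles, mixed_cycles,
                    raw_weights)
  attr(res, "n_seq") <- n_min:n_max
  attr(res, "samples") <- names(factors)
  res
}

# leaf_hap convention differs between engines: cpp uses 0-based hap where
# hap 0 feeds agg1; R state uses hap 1 -> T1.  Both orderings agree because
# labels "_1" map to haplotype 1 in each case.

#' Estimate repeat numbers jointly over a tree ensemble
#'
#' End-to-end estimator: builds diploid insert-size factors, runs
#' `loopy_cycles` cycles of loopy BP followed by `mixed_cycles` cycles of
#' mixed-product BP over the ensemble, and decodes per-haplotype calls.
#' Deterministic given its inputs.
#'
#' @param obs_by_individual Named list (sample id) of observation data
#'   frames (columns `s`, `e` or `s`, `l`).  Individuals present in the
#'   ensemble but absent here (or with zero rows) contribute a flat
#'   factor.
#' @param ensemble List of [coalescent_tree()]s with leaf labels
#'   `"<sample>_1"`/`"<sample>_2"`.
#' @param region An [str_region()].
#' @param F An [insert_dist()].
#' @param params A [mutation_params()].
#' @param n_min,n_max Repeat-state grid (defaults 0 and 40).
#' @param loopy_cycles,mixed_cycles Cycle counts (defaults 10 and 10).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical results up to floating-point noise).
#' @param table Optional precomputed normalization table.
#' @return A list: `calls` (the [decode()]d `repeat_callset`),
#'   `messages` (final cross/tree-aggregate messages), `factors`.
#' @export
estimate_repeats <- function(obs_by_individual, ensemble, region, F, params,
                             n_min = 0L, n_max = 40L,
                             loopy_cycles = 10L, mixed_cycles = 10L,
                             engine = c("cpp", "r"), table = NULL) {
  engine <- match.arg(engine)
  leaf_labels <- ensemble[[1]]$labels
  samples <- sort(unique(sub("_[12]$", "", leaf_labels)))
  missing_samples <- setdiff(names(obs_by_individual), samples)
  if (length(missing_samples)) {
    stop("observations without matching tree leaves: ",
         paste(missing_samples, collapse = ", "))
  }
  if (is.null(table)) table <- build_normalization_table(region, F, n_min, n_max)
  factors <- lapply(samples, function(s) {
    obs <- obs_by_individual[[s]]
    if (is.null(obs)) obs <- data.frame(s = integer(0), l = integer(0))
    build_diploid_factor(obs, region, F, n_min, n_max, table = table)
  })
  names(factors) <- samples
  res <- bp_infer(factors, ensemble, params, n_min, n_max,
                  loopy_cycles, mixed_cycles, engine)
  calls <- decode(res, n_r = region$n_r, factors = factors)
  list(calls = calls, messages = res, factors = factors)
}

#' Run multi-tree BP from prebuilt factor tables
#'
#' Lower-level entry point used by [estimate_repeats()] and the rate
#' selection: runs the requested loopy and mixed-product cycles and
#' returns the final cross-haplotype messages and normalized tree
#' aggregates, ready for [decode()] or [rate_score()].
#'
#' @inheritParams init_bp_state
#' @param loopy_cycles,mixed_cycles Cycle counts.
#' @param engine `"cpp"` or `"r"`.
#' @return List `m12`, `m21`, `agg1`, `agg2` (`S x I` matrices) with
#'   attributes `n_seq` and `samples`.
#' @export
bp_infer <- function(factors, ensemble, params, n_min = 0L, n_max = 40L,
                     loopy_cycles = 10L, mixed_cycles = 10L,
                     engine = c("cpp", "r"), aggregate = c("normalized", "raw")) {
  engine <- match.arg(engine)
  aggregate <- match.arg(aggregate)
  if (aggregate == "raw" && engine == "r") {
    stop("raw-scale aggregation is only available in the compiled engine")
  }
  if (engine == "cpp") {
    .bp_cpp_run(factors, ensemble, params, n_min, n_max,
                loopy_cycles, mixed_cycles, aggregate == "raw")
  } else {
    state <- init_bp_state(factors, ensemble, params, n_min, n_max)
    state <- run_loopy(state, loopy_cycles)
    state <- run_mixed_product(state, mixed_cycles)
    state <- .bp_aggregate(state)
    res <- list(m12 = state$m12, m21 = state$m21,
                agg1 = state$T1, agg2 = state$T2)
    attr(res, "n_seq") <- state$n_seq
    attr(res, "samples") <- state$samples
    res
  }
}

#' Exact marginal-MAP oracle by exhaustive enumeration
#'
#' Enumerates every assignment of leaf repeat numbers, computing for each
#' the objective `prod_i f_i(n_i1, n_i2) * sum_g P(N | g)` with the
#' internal-node summation done by exact elimination per tree.  Intended
#' as a test oracle on tiny instances only.
#'
#' @param factors Named list of diploid factor tables.
#' @param ensemble Tree ensemble.
#' @param params A [mutation_params()].
#' @param n_min,n_max Repeat-state grid.
#' @param max_configs Refuse when the leaf state space exceeds this.
#' @return List: `calls` (data frame `sample`, `n1`, `n2`), `objective`,
#'   and `objective_fn(n1_vec, n2_vec)` for scoring arbitrary
#'   configurations.
#' @export
brute_force_marginal_map <- function(factors, ensemble, params,
                                     n_min = 0L, n_max = 40L,
                                     max_configs = 1e7) {
  samples <- names(factors)
  I <- length(samples)
  n_seq <- n_min:n_max
  S <- length(n_seq)
  if (S^(2 * I) > max_configs) stop("state space too large for brute force")
  cache <- transition_cache()
  specs <- lapply(ensemble, function(tr) {
    bt <- branch_times(tr)
    M <- vector("list", 2L * tr$n_leaf - 1L)
    for (v in seq_along(M)) {
      if (!is.na(tr$parent[v])) {
        M[[v]] <- unclass(build_transition_matrix(bt[v], params, n_min, n_max, cache))
      }
    }
    hap <- as.integer(sub("^.*_", "", tr$labels))
    list(tree = tr, M = M, postorder = .postorder(tr),
         leaf_col = match(sub("_[12]$", "", tr$labels), samples) * 2L - 2L + hap)
  })
  # P(N | g) by elimination with leaves clamped; leaf_states indexed 1..S
  tree_prob <- function(spec, leaf_states) {
    tr <- spec$tree
    partial <- matrix(0, S, 2L * tr$n_leaf - 1L)
    for (v in seq_len(tr$n_leaf)) partial[leaf_states[spec$leaf_col[v]], v] <- 1
    for (v in spec$postorder) {
      if (v <= tr$n_leaf) next
      ch <- .tree_children(tr, v)
      partial[, v] <- as.numeric(crossprod(spec$M[[ch[1]]], partial[, ch[1]])) *
        as.numeric(crossprod(spec$M[[ch[2]]], partial[, ch[2]]))
    }
    sum(partial[, tr$root])
  }
  objective_fn <- function(n1_vec, n2_vec) {
    ls <- integer(2L * I)
    ls[seq(1L, 2L * I, 2L)] <- match(n1_vec, n_seq)
    ls[seq(2L, 2L * I, 2L)] <- match(n2_vec, n_seq)
    fac <- prod(vapply(seq_len(I), function(i) {
      factors[[i]][ls[2L * i - 1L], ls[2L * i]]
    }, numeric(1)))
    fac * sum(vapply(specs, tree_prob, numeric(1), leaf_states = ls))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), 2L * I)))
  best_val <- -Inf; best_row <- NULL
  for (r in seq_len(nrow(grid))) {
    ls <- grid[r, ]
    v <- objective_fn(n_seq[ls[seq(1L, 2L * I, 2L)]],
                      n_seq[ls[seq(2L, 2L * I, 2L)]])
    if (v > best_val) { best_val <- v; best_row <- ls }
  }
  calls <- data.frame(sample = samples,
                      n1 = n_seq[best_row[seq(1L, 2L * I, 2L)]],
                      n2 = n_seq[best_row[seq(2L, 2L * I, 2L)]])
  list(calls = calls, objective = best_val, objective_fn = objective_fn)
}
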