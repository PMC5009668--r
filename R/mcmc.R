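#' Sample coalescent trees from phased genotypes by MCMC
#'
#' A Metropolis-Hastings sampler over rooted ultrametric binary genealogies
#' of the panel haplotypes.  The target is the Kingman coalescent prior on
#' (topology, node times) multiplied by the likelihood of the phased
#' biallelic sites under a two-state symmetric substitution model
#' (Felsenstein pruning, stationary root).  Two move types alternate at
#' random:
#'
#' * node-time move: a uniform redraw of one internal node's time inside
#'   the window allowed by its children and parent (an exponential
#'   extension beyond the older child for the root);
#' * subtree exchange: two compatible subtrees (neither ancestral to the
#'   other, each younger than the other's parent) swap their attachment
#'   points, preserving all node times.
#'
#' This is a deliberately simple sampler: the estimator downstream only
#' consumes the sampled ensemble, and with a flat likelihood the sampler
#' reproduces coalescent-prior statistics (tested).  Default chain
#' settings are burn-in 50,000, thinning 100, and 100 retained trees;
#' thinning counts iterations (accepted or rejected).
#'
#' @param panel A [haplotype_panel()]; rows are the tree leaves.
#' @param params A [mutation_params()] (supplies `Ne`).
#' @param n_samples Number of trees to retain.
#' @param burn_in Iterations discarded before sampling.
#' @param thin Iterations between retained trees.
#' @param subst_rate Per-generation, per-site substitution rate of the
#'   likelihood model (default: transition + transversion,
#'   5.5e-8 + 1.2e-8).
#' @param init Optional starting `coalescent_tree` (default: a draw from
#'   the coalescent prior).
#' @return A list of `coalescent_tree`s (the tree ensemble), with
#'   attribute `acceptance` giving per-move acceptance rates.
#' @export
sample_trees_mcmc <- function(panel, params, n_samples = 100L,
                              burn_in = 50000L, thin = 100L,
                              subst_rate = 6.7e-8, init = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  n <- nrow(panel$alleles)
  if (n < 2L) stop("panel must contain at least two haplotypes")
  labels <- rownames(panel$alleles)

  # site-pattern compression: identical columns share one pruning pass
  key <- apply(panel$alleles, 2, paste, collapse = "")
  pat_idx <- !duplicated(key)
  patterns <- panel$alleles[, pat_idx, drop = FALSE]
  weights <- as.numeric(table(key)[key[pat_idx]])
  R_site <- subst_rate * params$Ne          # substitution rate per Ne-unit

  tree <- if (is.null(init)) simulate_coalescent_tree(n, labels = labels) else init
  if (!setequal(tree$labels, labels)) stop("init tree leaves must match the panel")
  parent <- tree$parent
  children <- tree$children
  time <- tree$time
  root <- tree$root
  n_nodes <- 2L * n - 1L
  internal <- (n + 1L):n_nodes

  loglik <- function() {
    bt <- time[parent] - time
    flip <- (1 - exp(-2 * R_site * bt)) / 2
    flip[is.na(flip)] <- 0
    int_order <- internal[order(time[internal])]
    cpp_pruning_loglik(children, int_order, flip, patterns, weights)
  }
  logprior <- function() {
    ts <- sort(time[internal])
    k <- seq(n, 2L)
    gaps <- diff(c(0, ts))
    -sum(k * (k - 1) / 4 * gaps)
  }
  subtree_nodes <- function(v) {
    out <- integer(0); stack <- v
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      out <- c(out, x)
      if (x > n) stack <- c(stack, children[, x - n])
    }
    out
  }
  # partners b with which subtree a may be exchanged (times preserved)
  valid_partners <- function(a) {
    cand <- setdiff(which(!is.na(parent)), a)
    cand <- cand[parent[cand] != parent[a]]
    cand <- cand[time[parent[cand]] > time[a] & time[parent[a]] > time[cand]]
    bad <- c(subtree_nodes(a), .ancestors(a, parent))
    setdiff(cand, bad)
  }

  cur_ll <- loglik(); cur_lp <- logprior()
  acc <- c(time = 0L, topo = 0L); tries <- c(time = 0L, topo = 0L)
  total_iter <- burn_in + n_samples * thin
  out <- vector("list", n_samples)
  got <- 0L

  for (it in seq_len(total_iter)) {
    if (stats::runif(1) < 0.5) {                      # node-time move
      tries["time"] <- tries["time"] + 1L
      v <- if (length(internal) == 1L) internal else sample(internal, 1L)
      old_t <- time[v]
      lo <- max(time[children[, v - n]])
      log_q_ratio <- 0
      if (v == root) {
        new_t <- lo + stats::rexp(1L, rate = 0.5)
        log_q_ratio <- stats::dexp(old_t - lo, 0.5, log = TRUE) -
          stats::dexp(new_t - lo, 0.5, log = TRUE)
      } else {
        hi <- time[parent[v]]
        new_t <- stats::runif(1L, lo, hi)
      }
      time[v] <- new_t
      new_ll <- loglik(); new_lp <- logprior()
      if (log(stats::runif(1)) < new_ll + new_lp - cur_ll - cur_lp + log_q_ratio) {
        cur_ll <- new_ll; cur_lp <- new_lp
        acc["time"] <- acc["time"] + 1L
      } else {
        time[v] <- old_t
      }
    } else {                                          # subtree exchange
      tries["topo"] <- tries["topo"] + 1L
      a <- sample(setdiff(seq_len(n_nodes), root), 1L)
      Va <- valid_partners(a)
      if (length(Va) > 0L) {
        b <- if (length(Va) == 1L) Va else sample(Va, 1L)
        nb_fwd <- 1 / length(Va) + 1 / length(valid_partners(b))
        pa <- parent[a]; pb <- parent[b]
        .swap <- function() {
          parent[a] <<- pb; parent[b] <<- pa
          children[children[, pa - n] == a, pa - n] <<- b
          children[children[, pb - n] == b, pb - n] <<- a
          tmp <- pa; pa <<- pb; pb <<- tmp
        }
        .swap()
        nb_rev <- 1 / length(valid_partners(a)) + 1 / length(valid_partners(b))
        new_ll <- loglik()
        if (log(stats::runif(1)) < new_ll - cur_ll + log(nb_rev) - log(nb_fwd)) {
          cur_ll <- new_ll
          acc["topo"] <- acc["topo"] + 1L
        } else {
          .swap()
        }
      }
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      got <- got + 1L
      out[[got]] <- coalescent_tree(parent, children, time, labels)
    }
  }
  attr(out, "acceptance") <- acc / pmax(tries, 1L)
  out
}

# ancestors of node v (excluding v) under a parent vector
.ancestors <- function(v, parent) {
  out <- integer(0)
  p <- parent[v]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- parent[p]
  }
  out
}
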