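#' Simulation study configuration
#'
#' Collects the generative settings of the benchmark: a Kingman tree for
#' `2I` haplotypes (constant `Ne = 10400`), flanking biallelic sites at
#' human transition/transversion rates over +/-1000 bp, stepwise repeat
#' evolution from a root copy number of 25, and direct insert-size
#' simulation (mean 350 bp, sd 50 bp, read length 100 bp) at a target
#' read coverage.  `base_error` is recorded for provenance but unused:
#' read synthesis and alignment are replaced by direct simulation of the
#' inferred insert sizes.
#'
#' @param I Number of individuals.
#' @param coverage Read coverage per individual (e.g. 20 or 40).
#' @param mu_s True STR mutation rate per generation.
#' @param read_len Read length, bp.
#' @param insert_mean,insert_sd Insert-size distribution parameters, bp.
#' @param base_error Base substitution error fraction (recorded, unused).
#' @param Ne Effective population size.
#' @param root_repeat Repeat count at the tree root.
#' @param region Target [str_region()].
#' @param flank_bp Flanking window half-width for phased sites, bp.
#' @param replicates Number of simulation replicates.
#' @param seed RNG seed.
#' @param K Insert-size cap, bp.
#' @param n_min,n_max Estimation grid.
#' @param n_trees,burn_in,thin MCMC ensemble settings (defaults 100 /
#'   50000 / 100).
#' @param rate_grid Candidate STR mutation rates for selection; default
#'   the multiplicative grid around the true rate.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(I, coverage, mu_s,
                       read_len = 100L, insert_mean = 350, insert_sd = 50,
                       base_error = 0.001, Ne = 10400, root_repeat = 25L,
                       region = default_sim_region(), flank_bp = 1000L,
                       replicates = 10L, seed = 1L, K = 2000L,
                       n_min = 0L, n_max = 40L,
                       n_trees = 100L, burn_in = 50000L, thin = 100L,
                       rate_grid = NULL) {
  stopifnot(I >= 1, coverage > 0, read_len > 0, insert_mean > 0,
            insert_sd > 0, Ne > 0, root_repeat >= 1, flank_bp > 0,
            replicates >= 1)
  if (is.null(rate_grid)) rate_grid <- candidate_rates(mu_s)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate spanning-pair insert observations
#'
#' Per haplotype, fragment starts are laid down at density
#' `coverage / (2 * read_len)` per bp over the window `[s_m - K, s_m)`
#' (fragments starting at or beyond the region can never span it); the
#' fragment length is drawn Normal(`insert_mean`, `insert_sd`) rounded to
#' an integer.  A fragment is observed only when it spans the
#' individual's true allele (start strictly before `s_m`, end strictly
#' after the allele's region end `e_m + u (n - n_r)`).  The reported
#' insert size is the alignment-inferred one: true length minus
#' `u (n - n_r)`.
#'
#' @param true_repeats `I x 2` integer matrix of true diploid repeat
#'   numbers, row names = sample ids.
#' @param region An [str_region()].
#' @param coverage Read coverage.
#' @param read_len,insert_mean,insert_sd,K As in [sim_config()].
#' @return Named list of observation data frames (`s`, `e`, `l`).
#' @export
simulate_observations <- function(true_repeats, region, coverage,
                                  read_len = 100L, insert_mean = 350,
                                  insert_sd = 50, K = 2000L) {
  density <- coverage / (2 * read_len)
  window <- (region$s_m - K):(region$s_m - 1L)
  out <- vector("list", nrow(true_repeats))
  names(out) <- rownames(true_repeats)
  for (i in seq_len(nrow(true_repeats))) {
    obs_i <- list()
    for (h in 1:2) {
      n_true <- true_repeats[i, h]
      shift <- region$u * (n_true - region$n_r)
      n_frag <- stats::rpois(1L, density * length(window))
      if (n_frag == 0L) next
      s <- sample(window, n_frag, replace = TRUE)
      l_true <- as.integer(round(stats::rnorm(n_frag, insert_mean, insert_sd)))
      span <- (s + l_true) > (region$e_m + shift) & l_true > 0
      if (!any(span)) next
      l_obs <- l_true[span] - shift
      obs_i[[h]] <- data.frame(s = s[span], e = s[span] + l_obs, l = l_obs)
    }
    obs_i <- do.call(rbind, obs_i)
    out[[i]] <- if (is.null(obs_i)) data.frame(s = integer(0), e = integer(0),
                                               l = integer(0)) else obs_i
  }
  out
}

#' Extract spanning read pairs from aligned-pair records
#'
#' Keeps records that (1) have concordant orientation (forward read on the
#' plus strand, reverse read on the minus strand), (2) start strictly
#' before the STR region start, and (3) end strictly after the STR region
#' end.
#'
#' @param records Data frame with columns `fwd_start`, `fwd_strand`,
#'   `rev_end`, `rev_strand` and optionally `sample_id`.
#' @param region An [str_region()].
#' @return Observation data frame (`s`, `e`, `l`, and `sample_id` when
#'   present), order-preserving.
#' @export
extract_spanning_pairs <- function(records, region) {
  records <- as.data.frame(records)
  keep <- records$fwd_strand == "+" & records$rev_strand == "-" &
    records$fwd_start < region$s_m & records$rev_end > region$e_m
  kept <- records[keep, , drop = FALSE]
  out <- data.frame(s = kept$fwd_start, e = kept$rev_end,
                    l = kept$rev_end - kept$fwd_start)
  if (!is.null(kept$sample_id)) out$sample_id <- kept$sample_id
  rownames(out) <- NULL
  out
}

#' Root-mean-squared error of diploid repeat calls
#'
#' For each individual the two estimated repeat numbers are matched to the
#' two true ones in the orientation minimizing the squared error, then
#' \deqn{RMSE = \sqrt{ \frac{1}{2I} \sum_i \min(matched, swapped) }.}
#'
#' @param true_calls,est_calls Data frames (or matrices) with columns
#'   `sample`, `n1`, `n2` (matrices: row names as samples).
#' @return A list of class `evaluation_result`: `rmse`,
#'   `per_individual` (named vector of per-individual summed squared
#'   errors under the best pairing).
#' @export
rmse <- function(true_calls, est_calls) {
  tc <- .as_calls(true_calls)
  ec <- .as_calls(est_calls)
  if (!setequal(tc$sample, ec$sample)) {
    stop("true and estimated call sets cover different individuals")
  }
  ec <- ec[match(tc$sample, ec$sample), ]
  d_match <- (tc$n1 - ec$n1)^2 + (tc$n2 - ec$n2)^2
  d_swap <- (tc$n1 - ec$n2)^2 + (tc$n2 - ec$n1)^2
  per <- pmin(d_match, d_swap)
  names(per) <- tc$sample
  structure(list(rmse = sqrt(mean(per) / 2), per_individual = per),
            class = "evaluation_result")
}

.as_calls <- function(x) {
  if (is.matrix(x)) {
    data.frame(sample = rownames(x), n1 = x[, 1], n2 = x[, 2])
  } else {
    as.data.frame(x)[, c("sample", "n1", "n2")]
  }
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("RMSE = %.4f over %d individuals\n", x$rmse,
              length(x$per_individual)))
  invisible(x)
}

#' Basic-model calls for a cohort
#'
#' Runs [basic_model_estimate()] per individual; individuals without
#' spanning pairs receive the reference call `(n_r, n_r)`.
#'
#' @param obs_by_individual Named list of observation data frames.
#' @inheritParams basic_model_estimate
#' @return A data frame `sample`, `n1`, `n2`, `loglik`.
#' @export
basic_model_cohort <- function(obs_by_individual, region, F,
                               n_min = 0L, n_max = 40L, table = NULL) {
  if (is.null(table)) table <- build_normalization_table(region, F, n_min, n_max)
  res <- lapply(names(obs_by_individual), function(s) {
    obs <- .as_obs(obs_by_individual[[s]])
    if (nrow(obs) == 0L) {
      data.frame(sample = s, n1 = region$n_r, n2 = region$n_r,
                 loglik = NA_real_)
    } else {
      call <- basic_model_estimate(obs, region, F, n_min, n_max, table = table)
      data.frame(sample = s, n1 = call$n1, n2 = call$n2, loglik = call$loglik)
    }
  })
  do.call(rbind, res)
}

#' Coalescent-coupled calls for a cohort
#'
#' Convenience wrapper: builds factors, optionally selects the STR
#' mutation rate by message agreement over `rate_grid`, then runs the
#' multi-tree BP estimator.
#'
#' @inheritParams estimate_repeats
#' @param rate_grid Candidate mutation rates; a single value skips
#'   selection.
#' @param Ne Effective population size.
#' @return List: `calls`, `mu_s` (selected rate), `scores` (rate-selection
#'   table or `NULL`).
#' @export
coalescent_cohort <- function(obs_by_individual, ensemble, region, F,
                              rate_grid, Ne = 10400, n_min = 0L, n_max = 40L,
                              loopy_cycles = 10L, mixed_cycles = 10L,
                              engine = "cpp", table = NULL) {
  if (is.null(table)) table <- build_normalization_table(region, F, n_min, n_max)
  samples <- sort(unique(sub("_[12]$", "", ensemble[[1]]$labels)))
  factors <- lapply(samples, function(s) {
    obs <- obs_by_individual[[s]]
    if (is.null(obs)) obs <- data.frame(s = integer(0), l = integer(0))
    build_diploid_factor(obs, region, F, n_min, n_max, table = table)
  })
  names(factors) <- samples
  scores <- NULL
  if (length(rate_grid) > 1L) {
    sel <- select_rate(rate_grid, factors, ensemble, Ne = Ne,
                       n_min = n_min, n_max = n_max,
                       loopy_cycles = loopy_cycles, engine = engine)
    mu_s <- sel$mu_s
    scores <- sel$scores
  } else {
    mu_s <- rate_grid
  }
  params <- mutation_params(mu_s, Ne)
  res <- bp_infer(factors, ensemble, params, n_min, n_max,
                  loopy_cycles, mixed_cycles, engine)
  calls <- decode(res, n_r = region$n_r, factors = factors)
  list(calls = calls, mu_s = mu_s, scores = scores)
}

#' Run the end-to-end simulation study
#'
#' Per replicate: simulate a Kingman genealogy, flanking phased sites and
#' stepwise repeat truth; simulate spanning-pair observations; run the
#' requested estimators; score each with [rmse()].  `"basic"` is the
#' per-individual grid search; `"coalescent"` samples a tree ensemble from
#' the panel by MCMC and runs the multi-tree BP estimator with rate
#' selection; `"shuffled"` does the same from a randomly
#' haplotype-shuffled panel (the negative control for the genealogy).
#'
#' @param config A [sim_config()].
#' @param methods Subset of `c("basic", "coalescent", "shuffled")`.
#' @param verbose Print per-replicate progress.
#' @return A list of class `sim_study`: `per_replicate` (data frame
#'   `replicate`, `method`, `rmse`, `mu_s`), `mean_rmse` (named vector),
#'   `config`.
#' @export
run_simulation_study <- function(config,
                                 methods = c("basic", "coalescent", "shuffled"),
                                 verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(config$seed)
  region <- config$region
  F <- normal_insert_dist(config$insert_mean, config$insert_sd, config$K)
  table <- build_normalization_table(region, F, config$n_min, config$n_max)
  positions <- c((region$s_m - config$flank_bp):(region$s_m - 1L),
                 (region$e_m + 1L):(region$e_m + config$flank_bp))
  params_true <- mutation_params(config$mu_s, config$Ne)
  rows <- list()
  for (rep_i in seq_len(config$replicates)) {
    tree <- simulate_coalescent_tree(2L * config$I)
    panel <- mutate_sites_on_tree(tree, positions, params = params_true)
    assign_n <- simulate_repeat_numbers(tree, config$root_repeat, params_true)
    truth <- leaf_truth_matrix(assign_n, tree$labels)
    obs <- simulate_observations(truth, region, config$coverage,
                                 config$read_len, config$insert_mean,
                                 config$insert_sd, config$K)
    add <- function(method, value, mu = NA_real_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        replicate = rep_i, method = method, rmse = value, mu_s = mu)
    }
    if ("basic" %in% methods) {
      calls <- basic_model_cohort(obs, region, F, config$n_min, config$n_max,
                                  table = table)
      add("basic", rmse(truth, calls)$rmse)
    }
    for (method in intersect(methods, c("coalescent", "shuffled"))) {
      pan <- if (method == "shuffled") shuffle_haplotypes(panel) else panel
      ensemble <- sample_trees_mcmc(pan, params_true,
                                    n_samples = config$n_trees,
                                    burn_in = config$burn_in,
                                    thin = config$thin)
      fit <- coalescent_cohort(obs, ensemble, region, F,
                               rate_grid = config$rate_grid, Ne = config$Ne,
                               n_min = config$n_min, n_max = config$n_max,
                               table = table)
      add(method, rmse(truth, fit$calls)$rmse, fit$mu_s)
    }
    if (verbose) {
      last <- do.call(rbind, rows)
      message(sprintf("replicate %d/%d done: %s", rep_i, config$replicates,
                      paste(sprintf("%s=%.2f",
                                    last$method[last$replicate == rep_i],
                                    last$rmse[last$replicate == rep_i]),
                            collapse = " ")))
    }
  }
  per <- do.call(rbind, rows)
  structure(list(per_replicate = per,
                 mean_rmse = tapply(per$rmse, per$method, mean),
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("simulation study: I = %d, coverage = %gx, mu_s = %g, %d replicates\n",
              x$config$I, x$config$coverage, x$config$mu_s,
              x$config$replicates))
  for (m in names(x$mean_rmse)) {
    cat(sprintf("  mean RMSE %-11s %.3f\n", paste0(m, ":"), x$mean_rmse[[m]]))
  }
  invisible(x)
}
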