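#' STR mutation-rate selection by message agreement
#'
#' After loopy BP, the read-derived message to each haplotype
#' (`m_{i2->i1}`) and the genealogy-derived message (the normalized tree
#' aggregate) should agree when the assumed STR mutation rate is right.
#' The agreement score is the sum over individuals of the two dot products
#' \deqn{\sum_i \left( \sum_n \bar m_{i_2 \to i_1}(n) \bar m_{G \to i_1}(n)
#'   + \sum_n \bar m_{i_1 \to i_2}(n) \bar m_{G \to i_2}(n) \right),}
#' all message vectors normalized to sum one.  Each dot product lies in
#' `[0, 1]`, so the score lies in `[0, 2I]`; a candidate grid of rates is
#' scored and the argmax selected (ties to the smaller rate).
#'
#' @name rate_selection
NULL

#' Message-agreement score of a loopy-BP result
#'
#' @param result A `bp_state` after [run_loopy()], or the message list
#'   returned in `estimate_repeats(...)$messages`.
#' @return The scalar score in `[0, 2I]`.
#' @export
rate_score <- function(result) {
  if (inherits(result, "bp_state")) {
    result <- .bp_aggregate(result)
    result <- list(m12 = result$m12, m21 = result$m21,
                   agg1 = result$T1, agg2 = result$T2)
  }
  sum(result$m21 * result$agg1) + sum(result$m12 * result$agg2)
}

#' Select an STR mutation rate from a candidate grid
#'
#' Runs `loopy_cycles` cycles of loopy BP for every candidate rate over a
#' shared factor set and tree ensemble, scores each with [rate_score()],
#' and returns the best rate (ties broken toward the smaller rate).  The
#' default candidate grid is `{1e-4, 5e-4, 1e-3, 5e-3, 1e-2}`; when a
#' reference rate is known, `candidate_rates(ref)` supplies the
#' multiplicative grid `{0.01, 0.1, 0.5, 0.75, 1, 1.2, 2, 5, 10, 100} * ref`.
#'
#' @param candidates Numeric vector of candidate per-generation rates.
#' @param factors Named list of diploid factor tables
#'   ([build_diploid_factor()]).
#' @param ensemble Tree ensemble.
#' @param Ne Effective population size.
#' @param n_min,n_max Repeat-state grid.
#' @param loopy_cycles Loopy cycles per candidate (default 10).
#' @param engine `"cpp"` or `"r"`.
#' @return List: `mu_s` (selected rate) and `scores`
#'   (data frame `mu_s`, `score`).
#' @export
select_rate <- function(candidates, factors, ensemble, Ne = 10400,
                        n_min = 0L, n_max = 40L, loopy_cycles = 10L,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(candidates) == 0L) stop("candidate rate list must be non-empty")
  scores <- vapply(candidates, function(mu) {
    params <- mutation_params(mu, Ne)
    rate_score(bp_infer(factors, ensemble, params, n_min, n_max,
                        loopy_cycles, 0L, engine))
  }, numeric(1))
  ord <- order(-scores, candidates)
  list(mu_s = candidates[ord[1]],
       scores = data.frame(mu_s = candidates, score = scores))
}

#' @rdname select_rate
#' @param reference_rate Optional known rate; when supplied the
#'   multiplicative simulation grid is returned, otherwise the default
#'   absolute grid.
#' @export
candidate_rates <- function(reference_rate = NULL) {
  if (is.null(reference_rate)) {
    c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2)
  } else {
    c(0.01, 0.1, 0.5, 0.75, 1, 1.2, 2, 5, 10, 100) * reference_rate
  }
}
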