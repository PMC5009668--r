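#' Tabular I/O for observations and calls
#'
#' Observations travel as TSV with header `sample_id`, `s`, `e`
#' (forward-read start and reverse-read end, 1-based); calls as TSV with
#' header `sample_id`, `n_hat_1`, `n_hat_2` plus optional extras.
#'
#' @param path File path.
#' @return `read_observations_tsv` returns a named list of observation
#'   data frames (one per sample); writers return `path` invisibly.
#' @export
read_observations_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "s", "e") %in% names(tab))) {
    stop("observations TSV needs columns sample_id, s, e")
  }
  tab$l <- tab$e - tab$s
  split(tab[, c("s", "e", "l")], tab$sample_id)
}

#' @rdname read_observations_tsv
#' @param obs_by_individual Named list of observation data frames.
#' @export
write_observations_tsv <- function(obs_by_individual, path) {
  rows <- lapply(names(obs_by_individual), function(sid) {
    obs <- .as_obs(obs_by_individual[[sid]])
    if (nrow(obs) == 0L) return(NULL)
    data.frame(sample_id = sid, s = obs$s, e = obs$s + obs$l)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(sample_id = character(0),
                                      s = integer(0), e = integer(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_observations_tsv
#' @param calls A `repeat_callset` or data frame with columns `sample`,
#'   `n1`, `n2` (optionally `belief1`, `belief2`) or a truth matrix.
#' @param mu_s Optional selected mutation rate recorded in the output.
#' @export
write_calls_tsv <- function(calls, path, mu_s = NA_real_) {
  beliefs <- if (!is.null(calls$belief1)) {
    pmax(calls$belief1, calls$belief2)
  } else {
    NA_real_
  }
  calls <- .as_calls(calls)
  tab <- data.frame(sample_id = calls$sample, n_hat_1 = calls$n1,
                    n_hat_2 = calls$n2, belief_max = beliefs,
                    mu_s_selected = mu_s)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_observations_tsv
#' @export
read_calls_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(sample = tab$sample_id, n1 = tab$n_hat_1, n2 = tab$n_hat_2)
}
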