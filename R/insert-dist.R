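#' Insert-size distributions
#'
#' The insert-size distribution \eqn{F} is an empirical probability mass
#' function over integer fragment lengths `1..K`; lengths above the cap `K`
#' (and non-positive lengths) carry zero mass.  `K` defaults to 2000 bp,
#' which comfortably covers standard short-insert libraries.
#'
#' @param probs Numeric vector of probabilities for lengths `1..length(probs)`,
#'   or a named numeric vector whose names are integer lengths.
#' @param K Maximum insert size in bp.
#' @name insert_dist
NULL

#' Construct an insert-size distribution from probabilities
#'
#' @rdname insert_dist
#' @return An object of class `insert_dist`: a numeric vector of length `K`
#'   with `pmf[l]` the probability of insert length `l`.
#' @export
insert_dist <- function(probs, K = 2000L) {
  K <- as.integer(K)
  pmf <- numeric(K)
  if (!is.null(names(probs))) {
    lens <- as.integer(names(probs))
    keep <- lens >= 1L & lens <= K
    pmf[lens[keep]] <- pmf[lens[keep]] + as.numeric(probs[keep])
  } else {
    n <- min(length(probs), K)
    pmf[seq_len(n)] <- as.numeric(probs[seq_len(n)])
  }
  if (any(pmf < 0)) stop("insert-size probabilities must be non-negative")
  s <- sum(pmf)
  if (s <= 0) stop("insert-size distribution has zero total mass")
  if (abs(s - 1) > 1e-9) pmf <- pmf / s
  structure(pmf, K = K, class = "insert_dist")
}

#' Evaluate F(l), returning 0 outside 1..K
#'
#' @param F An `insert_dist`.
#' @param l Integer insert lengths (vectorized).
#' @return Probabilities, zero for `l <= 0` or `l > K`.
#' @export
insert_pmf <- function(F, l) {
  K <- attr(F, "K")
  out <- numeric(length(l))
  ok <- l >= 1 & l <= K
  out[ok] <- unclass(F)[l[ok]]
  out
}

#' Discretized normal insert-size distribution
#'
#' The simulation study draws fragment lengths from Normal(mean, sd) rounded
#' to the nearest integer; this constructor builds the matching pmf on
#' `1..K` (mass of each integer bin, renormalized after truncation).
#'
#' @param mean,sd Insert-size mean and standard deviation in bp.
#' @param K Maximum insert size in bp.
#' @return An `insert_dist`.
#' @export
normal_insert_dist <- function(mean = 350, sd = 50, K = 2000L) {
  l <- seq_len(K)
  p <- stats::pnorm(l + 0.5, mean, sd) - stats::pnorm(l - 0.5, mean, sd)
  insert_dist(p, K = K)
}

#' Estimate an empirical insert-size distribution from observed lengths
#'
#' @param lengths Integer vector of observed insert sizes (e.g. absolute
#'   template lengths of concordant pairs genome-wide).
#' @param K Maximum insert size; longer observations are dropped and the
#'   mass renormalized.
#' @param min_lengths Minimum number of usable lengths required.
#' @param smooth_window Odd moving-average window applied to the pmf
#'   (1 = no smoothing).
#' @return An `insert_dist`.
#' @export
estimate_insert_distribution <- function(lengths, K = 2000L, min_lengths = 100L,
                                         smooth_window = 1L) {
  lengths <- as.integer(round(lengths))
  lengths <- lengths[lengths >= 1L & lengths <= K]
  if (length(lengths) < min_lengths) {
    stop(sprintf(
      "only %d usable insert lengths (< %d); consider the parametric normal_insert_dist() fallback",
      length(lengths), min_lengths))
  }
  pmf <- tabulate(lengths, nbins = K) / length(lengths)
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
    kern <- rep(1 / smooth_window, smooth_window)
    pmf <- stats::filter(pmf, kern, sides = 2)
    pmf[is.na(pmf)] <- 0
    pmf <- as.numeric(pmf)
  }
  insert_dist(pmf, K = K)
}

#' Read / write an insert-size distribution as two-column TSV
#'
#' Columns `length` and `probability`, header required.
#' @param path File path.
#' @param K Maximum insert size for the constructed distribution.
#' @return `read_insert_dist` returns an `insert_dist`;
#'   `write_insert_dist` returns `path` invisibly.
#' @export
read_insert_dist <- function(path, K = 2000L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("length", "probability") %in% names(tab))) {
    stop("insert distribution TSV needs columns 'length' and 'probability'")
  }
  p <- tab$probability
  names(p) <- tab$length
  insert_dist(p, K = K)
}

#' @rdname read_insert_dist
#' @param F An `insert_dist` to write.
#' @export
write_insert_dist <- function(F, path) {
  pmf <- unclass(F)
  nz <- which(pmf > 0)
  utils::write.table(
    data.frame(length = nz, probability = pmf[nz]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
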