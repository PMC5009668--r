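#' Define an STR region
#'
#' An STR region is the reference-genome interval occupied by the tandem
#' repeat tract, together with the repeat-unit length and the repeat copy
#' number present in the reference sequence.  Coordinates are 1-based and
#' inclusive on both ends.
#'
#' @param chrom Chromosome name.
#' @param start,end First and last base of the repeat tract (1-based,
#'   inclusive).
#' @param unit Repeat-unit length in bp (e.g. 4 for a TTTC repeat).
#' @param ref_repeat Copy number of the unit in the reference genome.
#' @param id Optional region label.
#'
#' @return An object of class `str_region` with fields `chrom`, `s_m`
#'   (start), `e_m` (end), `u` (unit length), `n_r` (reference repeat
#'   number) and `id`.
#'
#' @details A warning (not an error) is raised when `unit * ref_repeat`
#'   differs from the tract length by more than one unit; reference repeat
#'   tracts frequently end in a partial unit so small discrepancies are
#'   expected.
#'
#' @examples
#' str_region("chr7", 127898719, 127898787, unit = 4, ref_repeat = 17)
#' @export
str_region <- function(chrom, start, end, unit, ref_repeat, id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  unit <- as.integer(unit); ref_repeat <- as.integer(ref_repeat)
  if (end < start) stop("STR region end must be >= start")
  if (unit < 1L) stop("repeat-unit length must be >= 1")
  len <- end - start + 1L
  if (abs(unit * ref_repeat - len) > unit) {
    warning(sprintf(
      "unit * ref_repeat = %d differs from region length %d by more than one unit",
      unit * ref_repeat, len))
  }
  structure(
    list(chrom = as.character(chrom), s_m = start, e_m = end,
         u = unit, n_r = ref_repeat,
         id = if (is.null(id)) sprintf("%s:%d-%d", chrom, start, end) else as.character(id)),
    class = "str_region")
}

#' @export
print.str_region <- function(x, ...) {
  cat(sprintf("STR region %s (%s:%d-%d), unit %d bp, reference repeat %d\n",
              x$id, x$chrom, x$s_m, x$e_m, x$u, x$n_r))
  invisible(x)
}

#' Read STR region definitions from a BED-like TSV
#'
#' The dialect used here has columns `chrom`, `start`, `end`, `unit`,
#' `ref_repeat`, `id` with a header line; `start`/`end` are 1-based
#' inclusive (unlike true BED, which is 0-based half-open).
#'
#' @param path Path to the TSV file.
#' @return A list of [str_region()] objects.
#' @export
read_str_regions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "unit", "ref_repeat", "id")
  if (!all(need %in% names(tab))) {
    stop("region file must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    str_region(tab$chrom[i], tab$start[i], tab$end[i], tab$unit[i],
               tab$ref_repeat[i], tab$id[i])
  })
}

#' The simulated benchmark STR region
#'
#' A TTTC tetranucleotide repeat on chromosome 7 (GRCh37
#' chr7:127898719-127898787, reference repeat number 17) used as the
#' default locus throughout the simulation study.
#'
#' @return An [str_region()].
#' @export
default_sim_region <- function() {
  str_region("chr7", 127898719L, 127898787L, unit = 4L, ref_repeat = 17L,
             id = "TTTC_chr7")
}
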