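#' Read spanning pairs from a SAM/BAM alignment
#'
#' Extracts concordant, properly oriented read pairs spanning the STR
#' region from a coordinate-sorted SAM or BAM file.  A pair is used when
#' its leftmost (forward) read is on the plus strand with a minus-strand
#' mate, both mates are mapped and primary, mapping quality is at least
#' `mapq`, and the template length is positive.  With `s` the forward-read
#' start and `TLEN` the SAM template length (inclusive span), the
#' reverse-read end is `s + TLEN - 1` and the inferred insert size
#' `l = e - s = TLEN - 1`.  The spanning filters of
#' [extract_spanning_pairs()] are then applied.
#'
#' SAM input is converted on the fly through `Rsamtools::asBam()`.
#'
#' @param path SAM or BAM file path.
#' @param region An [str_region()].
#' @param mapq Minimum mapping quality (default 20).
#' @return Observation data frame (`s`, `e`, `l`).
#' @export
read_spanning_pairs_sam <- function(path, region, mapq = 20L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for SAM/BAM ingestion")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isMinusStrand = FALSE, isMateMinusStrand = TRUE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flags,
                               what = c("pos", "isize", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$isize) & rec$isize > 0 &
    (is.na(rec$mapq) | rec$mapq >= mapq)
  s <- rec$pos[keep]
  e <- s + rec$isize[keep] - 1L
  extract_spanning_pairs(
    data.frame(fwd_start = s, fwd_strand = "+", rev_end = e,
               rev_strand = "-"),
    region)
}

#' Write observations as a minimal SAM fixture
#'
#' Emits one properly paired, plus/minus-oriented read pair per
#' observation (flags 99/147), with `TLEN = l + 1` so that
#' [read_spanning_pairs_sam()] round-trips the observations exactly.
#' Intended for tests and small fixtures, not production export.
#'
#' @param obs Observation data frame (`s`, `e` or `s`, `l`).
#' @param path Output SAM path.
#' @param region An [str_region()] (supplies the reference name).
#' @param read_len Read length written in the CIGAR/SEQ fields.
#' @param sample_id Read-group style prefix for read names.
#' @return `path`, invisibly.
#' @export
write_sam_pairs <- function(obs, path, region, read_len = 100L,
                            sample_id = "sim") {
  obs <- .as_obs(obs)
  con <- file(path, "w")
  on.exit(close(con))
  ref_len <- max(region$e_m + 10000L, if (nrow(obs)) max(obs$e) + read_len else 0L)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", region$chrom, ref_len)), con)
  if (nrow(obs) == 0L) return(invisible(path))
  seq_str <- paste(rep("A", read_len), collapse = "")
  cigar <- sprintf("%dM", read_len)
  ord <- order(obs$s)
  lines <- character(0)
  for (k in ord) {
    s <- obs$s[k]; e <- obs$e[k]; tlen <- obs$l[k] + 1L
    qname <- sprintf("%s_%06d", sample_id, k)
    rev_pos <- e - read_len + 1L
    lines <- c(lines,
      paste(qname, 99L, region$chrom, s, 60L, cigar, "=", rev_pos, tlen,
            seq_str, "*", sep = "\t"),
      paste(qname, 147L, region$chrom, rev_pos, 60L, cigar, "=", s, -tlen,
            seq_str, "*", sep = "\t"))
  }
  writeLines(lines, con)
  invisible(path)
}
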