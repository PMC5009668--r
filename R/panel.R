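#' Phased haplotype panels
#'
#' A haplotype panel holds phased biallelic alleles (0 = ancestral /
#' reference, 1 = derived / alternate) for the `2I` haplotypes of `I`
#' individuals at a set of flanking positions around an STR region.
#' Row `2i - 1` is haplotype 1 and row `2i` haplotype 2 of individual `i`;
#' row names follow the `"<sample>_1"` / `"<sample>_2"` convention.
#'
#' @param positions Integer site positions (bp).
#' @param alleles 0/1 matrix, haplotypes x sites.
#' @param labels Haplotype labels (row names); taken from `rownames(alleles)`
#'   when omitted.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(positions, alleles, labels = NULL) {
  alleles <- as.matrix(alleles)
  if (is.null(labels)) labels <- rownames(alleles)
  if (is.null(labels)) stop("haplotype labels required")
  if (nrow(alleles) %% 2L != 0L) stop("panel must have an even number of haplotype rows")
  if (ncol(alleles) != length(positions)) stop("positions/alleles dimension mismatch")
  if (!all(alleles %in% c(0L, 1L))) stop("panel alleles must be 0/1")
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- labels
  structure(list(positions = as.integer(positions), alleles = alleles),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  poly <- sum(apply(x$alleles, 2, function(a) length(unique(a)) > 1L))
  cat(sprintf("haplotype panel: %d haplotypes x %d sites (%d polymorphic)\n",
              nrow(x$alleles), ncol(x$alleles), poly))
  invisible(x)
}

#' Simulate biallelic flanking sites on a coalescent tree
#'
#' For every site and every branch, a substitution occurs with probability
#' `min(1, (transition_rate + transversion_rate) * Ne * t)` where `t` is
#' the branch time in `Ne`-generation units.  The root carries the
#' ancestral allele 0; repeated hits at a site toggle the allele back, so
#' sites stay biallelic.  Monomorphic sites are retained in the panel.
#'
#' @param tree A [coalescent_tree()].
#' @param positions Site positions (bp).
#' @param transition_rate,transversion_rate Per-generation, per-site
#'   substitution rates (defaults: human transition 5.5e-8 and
#'   transversion 1.2e-8).
#' @param params A [mutation_params()] (supplies `Ne`).
#' @return A [haplotype_panel()] over the tree's leaves.
#' @export
mutate_sites_on_tree <- function(tree, positions,
                                 transition_rate = 5.5e-8,
                                 transversion_rate = 1.2e-8,
                                 params = mutation_params(1e-3)) {
  if (length(positions) == 0L) stop("positions must be non-empty")
  total_rate <- transition_rate + transversion_rate
  S <- length(positions)
  nodes <- rev(.postorder(tree))                    # parents before children
  state <- matrix(0L, nrow = 2L * tree$n_leaf - 1L, ncol = S)
  bt <- branch_times(tree)
  for (v in nodes) {
    if (v == tree$root) next
    p_mut <- min(1, total_rate * params$Ne * bt[v])
    if (p_mut > 0) {
      flips <- stats::runif(S) < p_mut
      state[v, ] <- xor(state[tree$parent[v], ] == 1L, flips) * 1L
    } else {
      state[v, ] <- state[tree$parent[v], ]
    }
  }
  haplotype_panel(positions, state[seq_len(tree$n_leaf), , drop = FALSE],
                  labels = tree$labels)
}

#' Simulate stepwise repeat evolution down a coalescent tree
#'
#' The root receives `root_repeat`; each branch evolves the count with
#' [stepwise_simulate()] over `round(Ne * t)` generations.  Leaf values are
#' the simulation truth used for benchmarking.
#'
#' @param tree A [coalescent_tree()].
#' @param root_repeat Repeat count at the root (>= 1).
#' @param params A [mutation_params()].
#' @return Integer vector over all `2n - 1` nodes (class
#'   `repeat_assignment`); leaves are entries `1..n_leaf`, named by leaf
#'   label.
#' @export
simulate_repeat_numbers <- function(tree, root_repeat, params) {
  if (root_repeat < 1) stop("root repeat count must be >= 1")
  nodes <- rev(.postorder(tree))
  rep_n <- integer(2L * tree$n_leaf - 1L)
  rep_n[tree$root] <- as.integer(root_repeat)
  bt <- branch_times(tree)
  for (v in nodes) {
    if (v == tree$root) next
    g <- round(params$Ne * bt[v])
    rep_n[v] <- stepwise_simulate(rep_n[tree$parent[v]], g, params$mu_s)
  }
  names(rep_n) <- c(tree$labels, rep("", tree$n_leaf - 1L))
  structure(rep_n, class = "repeat_assignment")
}

#' Collect simulated leaf repeat numbers into a diploid truth matrix
#'
#' @param rep_n A `repeat_assignment` from [simulate_repeat_numbers()].
#' @param labels The tree's leaf labels (`"<sample>_1"` / `"<sample>_2"`).
#' @return `I x 2` integer matrix, row names = sample ids.
#' @export
leaf_truth_matrix <- function(rep_n, labels) {
  leaf <- rep_n[seq_along(labels)]
  samples <- unique(sub("_[12]$", "", labels))
  out <- matrix(NA_integer_, length(samples), 2,
                dimnames = list(samples, c("n1", "n2")))
  for (s in samples) {
    out[s, ] <- leaf[match(paste0(s, c("_1", "_2")), labels)]
  }
  out
}

#' Randomly shuffle the haplotypes of a panel
#'
#' Permutes the haplotype rows uniformly at random while keeping the row
#' labels in place, so each labelled haplotype receives another haplotype's
#' allele content.  This destroys the association between genotypes and
#' individuals and serves as the negative control for the genealogy
#' coupling.
#'
#' @param panel A [haplotype_panel()].
#' @return A shuffled `haplotype_panel`.
#' @export
shuffle_haplotypes <- function(panel) {
  perm <- sample(nrow(panel$alleles))
  shuffled <- panel$alleles[perm, , drop = FALSE]
  rownames(shuffled) <- rownames(panel$alleles)
  haplotype_panel(panel$positions, shuffled)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCFv4.2 with phased `GT` fields; REF/ALT are
#' placeholders (`A`/`T`) since only the 0/1 phase matters downstream.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path.
#' @param chrom Chromosome name for the records.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, chrom = "chr7") {
  labs <- rownames(panel$alleles)
  samples <- unique(sub("_[12]$", "", labs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (j in seq_along(panel$positions)) {
    gts <- vapply(samples, function(s) {
      a1 <- panel$alleles[match(paste0(s, "_1"), labs), j]
      a2 <- panel$alleles[match(paste0(s, "_2"), labs), j]
      paste0(a1, "|", a2)
    }, character(1))
    writeLines(paste(c(chrom, panel$positions[j], ".", "A", "T", ".", "PASS",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read phased genotypes from a VCF into a haplotype panel
#'
#' Accepts biallelic SNV records with phased `GT` only; unphased or
#' multi-allelic records are skipped (a message reports the count).
#'
#' @param path VCF path (uncompressed text).
#' @return A [haplotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("VCF is missing its #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  positions <- integer(0)
  rows <- list()
  skipped <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    ref <- f[4]; alt <- f[5]
    gt_idx <- match("GT", strsplit(f[9], ":")[[1]])
    gts <- vapply(f[-(1:9)], function(x) strsplit(x, ":")[[1]][gt_idx],
                  character(1), USE.NAMES = FALSE)
    if (nchar(ref) != 1L || nchar(alt) != 1L || alt %in% c(".", "") ||
        grepl(",", alt) || any(!grepl("^[01]\\|[01]$", gts))) {
      skipped <- skipped + 1L
      next
    }
    al <- unlist(lapply(gts, function(g) as.integer(strsplit(g, "|", fixed = TRUE)[[1]])))
    positions <- c(positions, as.integer(f[2]))
    rows[[length(rows) + 1L]] <- al
  }
  if (skipped > 0L) {
    message(skipped, " VCF records skipped (unphased, multi-allelic or non-SNV)")
  }
  if (length(rows) == 0L) stop("no usable phased biallelic records in VCF")
  alleles <- do.call(cbind, rows)
  labels <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
  haplotype_panel(positions, alleles, labels = labels)
}
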