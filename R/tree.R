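#' Coalescent tree objects
#'
#' A coalescent tree is a rooted, strictly binary, ultrametric genealogy of
#' the sampled haplotypes.  Leaves sit at time 0; each internal node is a
#' coalescence event at a strictly later (older) time.  Times are stored in
#' units of `Ne` generations (see [mutation_params()]).
#'
#' Internal representation: nodes `1..n` are leaves, `n+1..2n-1` internal;
#' `parent[v]` is the parent node id (`NA` for the root), `children` is a
#' `2 x (n-1)` matrix whose column `j` holds the children of internal node
#' `n + j`, and `time[v]` is the node's time before present.
#'
#' @param parent Integer parent vector.
#' @param children 2-column-per-internal-node child matrix.
#' @param time Node times.
#' @param labels Leaf labels (haplotype names, convention
#'   `"<sample>_1"` / `"<sample>_2"`).
#' @return An object of class `coalescent_tree`.
#' @export
coalescent_tree <- function(parent, children, time, labels) {
  tree <- structure(
    list(n_leaf = length(labels), labels = as.character(labels),
         parent = as.integer(parent), children = children,
         time = as.numeric(time)),
    class = "coalescent_tree")
  tree$root <- which(is.na(tree$parent))
  validate_coalescent_tree(tree)
  tree
}

#' Validate coalescent-tree invariants
#'
#' Checks: strictly binary with `n_leaf - 1` internal nodes, a single root,
#' leaves at time 0 (ultrametric), and every parent strictly older than its
#' children.
#'
#' @param tree A `coalescent_tree`.
#' @param tol Tolerance for the leaf-time check.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_coalescent_tree <- function(tree, tol = 1e-9) {
  n <- tree$n_leaf
  if (length(tree$parent) != 2L * n - 1L) stop("tree must have 2n-1 nodes")
  if (!identical(dim(tree$children), c(2L, n - 1L)) &&
      !all(dim(tree$children) == c(2, n - 1))) {
    stop("children matrix must be 2 x (n_leaf - 1)")
  }
  root <- which(is.na(tree$parent))
  if (length(root) != 1L || root <= n) stop("tree must have exactly one internal root")
  if (any(abs(tree$time[seq_len(n)]) > tol)) stop("leaves must sit at time 0")
  for (j in seq_len(n - 1L)) {
    v <- n + j
    ch <- tree$children[, j]
    if (any(tree$parent[ch] != v)) stop("parent/children tables disagree")
    if (any(tree$time[v] <= tree$time[ch])) {
      stop("parent nodes must be strictly older than their children")
    }
  }
  invisible(tree)
}

# children of internal node v
.tree_children <- function(tree, v) tree$children[, v - tree$n_leaf]

# node ids ordered children-before-parent; valid because parents are
# strictly older than children, so sorting by time is a postorder
.postorder <- function(tree) order(tree$time, seq_along(tree$time))

# branch time above each node (NA for root), Ne-generation units
branch_times <- function(tree) {
  out <- tree$time[tree$parent] - tree$time
  out
}

#' @export
print.coalescent_tree <- function(x, ...) {
  cat(sprintf("coalescent tree: %d leaves, TMRCA %.4f Ne-generations\n",
              x$n_leaf, max(x$time)))
  invisible(x)
}

#' Simulate a Kingman coalescent tree
#'
#' Standard neutral coalescent for a constant-size diploid population:
#' with `k` lineages the waiting time to the next coalescence is
#' Exponential with rate `k (k - 1) / 4` in `Ne`-generation units (so a
#' single pair coalesces after `2 Ne` generations on average), and the
#' merging pair is chosen uniformly.
#'
#' @param num_haplotypes Number of sampled haplotypes (tree leaves), >= 2.
#' @param labels Optional leaf labels; defaults to `"s<i>_1"`, `"s<i>_2"`
#'   pairs when `num_haplotypes` is even, else `"h<j>"`.
#' @return A [coalescent_tree()].
#' @export
simulate_coalescent_tree <- function(num_haplotypes, labels = NULL) {
  n <- as.integer(num_haplotypes)
  if (n < 2L) stop("need at least 2 haplotypes")
  if (is.null(labels)) {
    labels <- if (n %% 2L == 0L) {
      paste0(rep(sprintf("s%03d", seq_len(n %/% 2L)), each = 2L), "_", c(1L, 2L))
    } else {
      sprintf("h%03d", seq_len(n))
    }
  }
  parent <- rep(NA_integer_, 2L * n - 1L)
  children <- matrix(NA_integer_, 2L, n - 1L)
  time <- numeric(2L * n - 1L)
  active <- seq_len(n)
  t_now <- 0
  for (j in seq_len(n - 1L)) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1L, rate = k * (k - 1) / 4)
    pair <- sample(active, 2L)
    v <- n + j
    parent[pair] <- v
    children[, j] <- pair
    time[v] <- t_now
    active <- c(setdiff(active, pair), v)
  }
  coalescent_tree(parent, children, time, labels)
}

#' Newick import/export for coalescent trees
#'
#' Serialization goes through \pkg{ape}; branch lengths are node-time
#' differences in `Ne`-generation units.  `read_newick` rejects trees that
#' are not strictly binary, lack branch lengths, or are not ultrametric
#' within `tol`.
#'
#' @param tree A `coalescent_tree`.
#' @return `write_newick` returns a single Newick string;
#'   `read_newick` returns a `coalescent_tree`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(as_phylo(tree))
}

#' @rdname write_newick
#' @param text A Newick string.
#' @param tol Ultrametricity tolerance (max deviation of leaf depths).
#' @export
read_newick <- function(text, tol = 1e-6) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick: could not parse '", text, "'")
  from_phylo(phy, tol = tol)
}

#' Convert between `coalescent_tree` and ape's `phylo`
#'
#' @param tree A `coalescent_tree`.
#' @return `as_phylo` returns an ape `phylo`; `from_phylo` a
#'   `coalescent_tree`.
#' @export
as_phylo <- function(tree) {
  n <- tree$n_leaf
  # renumber internal nodes in preorder from the root (ape convention:
  # root = n + 1)
  new_id <- integer(2L * n - 1L)
  new_id[seq_len(n)] <- seq_len(n)
  stack <- tree$root
  nxt <- n + 1L
  order_int <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    new_id[v] <- nxt; nxt <- nxt + 1L
    order_int <- c(order_int, v)
    ch <- .tree_children(tree, v)
    stack <- c(stack, rev(ch[ch > n]))
  }
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  lens <- numeric(2L * (n - 1L))
  e <- 0L
  for (v in order_int) {
    for (ch in .tree_children(tree, v)) {
      e <- e + 1L
      edges[e, ] <- c(new_id[v], new_id[ch])
      lens[e] <- tree$time[v] - tree$time[ch]
    }
  }
  phy <- list(edge = edges, edge.length = lens, tip.label = tree$labels,
              Nnode = n - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' @rdname as_phylo
#' @param phy An ape `phylo` object.
#' @param tol Ultrametricity tolerance.
#' @export
from_phylo <- function(phy, tol = 1e-6) {
  n <- length(phy$tip.label)
  if (is.null(phy$edge.length)) stop("Newick tree must carry branch lengths")
  if (phy$Nnode != n - 1L) {
    stop("tree is not strictly binary (expected ", n - 1L, " internal nodes, got ",
         phy$Nnode, ")")
  }
  deg <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  if (any(deg[(n + 1L):(n + phy$Nnode)] != 2L)) {
    stop("tree is not strictly binary: an internal node lacks exactly two children")
  }
  # depths from the root, then times = max leaf depth - depth
  total <- n + phy$Nnode
  depth <- rep(NA_real_, total)
  root <- n + 1L
  depth[root] <- 0
  # edges in cladewise order have parents before children
  phy <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(phy$edge))) {
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + phy$edge.length[e]
  }
  leaf_depth <- depth[seq_len(n)]
  if (diff(range(leaf_depth)) > tol) {
    stop(sprintf("tree is not ultrametric: leaf depths span [%g, %g]",
                 min(leaf_depth), max(leaf_depth)))
  }
  h <- max(leaf_depth)
  time <- h - depth
  time[seq_len(n)] <- 0
  parent <- rep(NA_integer_, total)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- matrix(NA_integer_, 2L, n - 1L)
  for (v in (n + 1L):total) {
    children[, v - n] <- phy$edge[phy$edge[, 1] == v, 2]
  }
  coalescent_tree(parent, children, time, phy$tip.label)
}

#' Read / write tree ensembles (one Newick per line)
#'
#' @param trees A list of `coalescent_tree` objects (a tree ensemble).
#' @param path File path.
#' @return `read_tree_ensemble` returns a list of trees;
#'   `write_tree_ensemble` returns `path` invisibly.
#' @export
write_tree_ensemble <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

#' @rdname write_tree_ensemble
#' @param tol Ultrametricity tolerance.
#' @export
read_tree_ensemble <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty tree ensemble file")
  trees <- lapply(lines, read_newick, tol = tol)
  labs <- lapply(trees, function(tr) sort(tr$labels))
  if (length(unique(labs)) != 1L) stop("trees in an ensemble must share one leaf set")
  trees
}
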