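#' Rooted time-annotated gene genealogy
#'
#' A `gene_tree` is a rooted, possibly multifurcating genealogy with a
#' coalescence time attached to every node. Leaves are nodes `1..n_leaf` and
#' sit at time 0; internal nodes carry strictly positive times that increase
#' towards the root. Times are expressed in internal coalescent units of
#' 2*N_e generations, so a pair of lineages coalesces at rate 1 under a
#' constant-size population.
#'
#' @param parent integer vector, one entry per node; `parent[i]` is the node
#'   id of the parent of node `i`, or 0 for the root. Leaves occupy ids
#'   `1..n_leaf`, internal nodes the remaining ids.
#' @param time numeric vector of node times (leaves must be 0).
#' @param labels character vector of leaf labels (length `n_leaf`).
#' @param leaf_deme optional integer vector assigning each leaf to a
#'   subpopulation (used by the structured coalescent).
#' @return an object of class `gene_tree`.
#' @export
gene_tree <- function(parent, time, labels, leaf_deme = NULL) {
  n_leaf <- length(labels)
  parent <- as.integer(parent)
  stopifnot(length(parent) == length(time), n_leaf >= 1, n_leaf <= length(parent))
  if (sum(parent == 0L) != 1L) stop("gene_tree must have exactly one root")
  tr <- structure(list(parent = parent, time = as.numeric(time),
                       labels = as.character(labels), n_leaf = n_leaf,
                       leaf_deme = leaf_deme),
                  class = "gene_tree")
  validate_gene_tree(tr)
  tr
}

validate_gene_tree <- function(tr) {
  n <- tr$n_leaf
  m <- length(tr$parent)
  if (any(tr$time[seq_len(n)] != 0)) stop("leaf times must all be 0")
  root <- which(tr$parent == 0L)
  non_root <- setdiff(seq_len(m), root)
  if (any(tr$time[tr$parent[non_root]] < tr$time[non_root]))
    stop("node times must not decrease from child to parent")
  kids <- tabulate(tr$parent, nbins = m)
  if (any(kids[-seq_len(n)] < 2L))
    stop("every internal node needs at least 2 children")
  invisible(tr)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene_tree: %d leaves, %d internal nodes, TMRCA %.4g\n",
              x$n_leaf, length(x$parent) - x$n_leaf, max(x$time)))
  invisible(x)
}

n_leaves <- function(tr) tr$n_leaf

tree_root <- function(tr) which(tr$parent == 0L)

#' Children lists of every node
#' @noRd
tree_children <- function(tr) {
  m <- length(tr$parent)
  kids <- vector("list", m)
  idx <- which(tr$parent > 0L)
  sp <- split(idx, tr$parent[idx])
  kids[as.integer(names(sp))] <- sp
  kids
}

#' Nodes ordered so that every child precedes its parent (structural, does
#' not rely on node times being distinct)
#' @noRd
tree_postorder <- function(tr) {
  m <- length(tr$parent)
  kids <- tree_children(tr)
  out <- integer(m)
  k <- 0L
  stack <- tree_root(tr)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    stack <- c(stack, kids[[v]])
  }
  rev(out)
}

#' Leaf sets below every node
#'
#' @param tr a `gene_tree`.
#' @return list, indexed by node id, of sorted leaf index vectors.
#' @export
tree_clades <- function(tr) {
  m <- length(tr$parent)
  n <- tr$n_leaf
  kids <- tree_children(tr)
  out <- vector("list", m)
  out[seq_len(n)] <- as.list(seq_len(n))
  for (v in tree_postorder(tr)) {
    if (v <= n) next
    out[[v]] <- sort(unlist(out[kids[[v]]], use.names = FALSE))
  }
  out
}

#' Branch lengths (time to parent) per non-root node; root entry is NA
#' @noRd
tree_branch_lengths <- function(tr) {
  b <- rep(NA_real_, length(tr$parent))
  nz <- tr$parent > 0L
  b[nz] <- tr$time[tr$parent[nz]] - tr$time[nz]
  b
}

#' Total tree length in internal units
#' @export
tree_total_length <- function(tr) {
  b <- tree_branch_lengths(tr)
  sum(b, na.rm = TRUE)
}

#' Convert a gene_tree to an ape "phylo" object
#'
#' Branch lengths are time differences in internal coalescent units.
#'
#' @param tr a `gene_tree`.
#' @return an object of class `phylo`.
#' @export
as_phylo <- function(tr) {
  n <- tr$n_leaf
  m <- length(tr$parent)
  root <- tree_root(tr)
  ## renumber internal nodes in preorder so the root becomes n+1
  ord <- integer(m)
  ord[root] <- n + 1L
  nxt <- n + 2L
  stack <- root
  kids <- tree_children(tr)
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    ch <- kids[[v]]
    internal <- ch[ch > n]
    for (w in internal) {
      ord[w] <- nxt
      nxt <- nxt + 1L
    }
    stack <- c(stack, rev(internal))
  }
  ord[seq_len(n)] <- seq_len(n)
  child <- setdiff(seq_len(m), root)
  edge <- cbind(ord[tr$parent[child]], ord[child])
  len <- tr$time[tr$parent[child]] - tr$time[child]
  o <- order(edge[, 1L], edge[, 2L])
  structure(list(edge = edge[o, , drop = FALSE],
                 edge.length = len[o],
                 tip.label = tr$labels,
                 Nnode = m - n),
            class = "phylo", order = "cladewise")
}

#' Convert an ape "phylo" object to a gene_tree
#'
#' The tree must be ultrametric (all tips equidistant from the root) up to a
#' small numerical tolerance; tip times are snapped to 0.
#'
#' @param phy a `phylo` object with branch lengths.
#' @param tol relative tolerance for the ultrametricity check.
#' @return a `gene_tree` whose leaf order follows `phy$tip.label`.
#' @export
gene_tree_from_phylo <- function(phy, tol = 1e-6) {
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  parent <- integer(m)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  depth <- numeric(m)
  ## preorder over edges (cladewise order guarantees parents first)
  for (i in seq_len(nrow(phy$edge))) {
    e <- phy$edge[i, ]
    depth[e[2L]] <- depth[e[1L]] + phy$edge.length[i]
  }
  h <- max(depth[seq_len(n)])
  if (h > 0 && diff(range(depth[seq_len(n)])) > tol * max(h, 1))
    stop("tree is not ultrametric; cannot assign coalescence times")
  time <- h - depth
  time[seq_len(n)] <- 0
  gene_tree(parent, time, phy$tip.label)
}

#' Write a list of gene_trees to a Newick file (one tree per line)
#'
#' @param trees a list of `gene_tree` objects (or a `tree_sample`).
#' @param path output file path.
#' @export
write_trees_newick <- function(trees, path) {
  if (inherits(trees, "tree_sample")) trees <- trees$trees
  if (inherits(trees, "gene_tree")) trees <- list(trees)
  phys <- lapply(trees, as_phylo)
  class(phys) <- "multiPhylo"
  ape::write.tree(phys, file = path)
  invisible(path)
}

#' Read gene_trees from a Newick file
#'
#' @param path Newick file with one tree per line, branch lengths in internal
#'   coalescent units.
#' @return a list of `gene_tree` objects.
#' @export
read_trees_newick <- function(path) {
  phys <- ape::read.tree(path)
  if (inherits(phys, "phylo")) phys <- list(phys)
  lapply(phys, gene_tree_from_phylo)
}
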