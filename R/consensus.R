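## deterministic 31-bit integer weights used to fingerprint clades; sums of
## up to ~4e6 leaves stay exact in doubles (< 2^53)
clade_hash_weights <- function(n) {
  h1 <- numeric(n); h2 <- numeric(n)
  x <- 48271; y <- 16807
  for (i in seq_len(n)) {
    x <- (x * 48271) %% 2147483647
    y <- (y * 69621) %% 2147483647
    h1[i] <- x; h2[i] <- y
  }
  list(h1 = h1, h2 = h2)
}

## per-node clade fingerprints (size, sum h1, sum h2) via postorder sums
clade_signatures <- function(tr, hw) {
  m <- length(tr$parent)
  n <- tr$n_leaf
  s1 <- numeric(m); s2 <- numeric(m); sz <- numeric(m)
  s1[seq_len(n)] <- hw$h1; s2[seq_len(n)] <- hw$h2; sz[seq_len(n)] <- 1
  ord <- tree_postorder(tr)
  par <- tr$parent
  for (v in ord) {
    p <- par[v]
    if (p > 0L) {
      s1[p] <- s1[p] + s1[v]
      s2[p] <- s2[p] + s2[v]
      sz[p] <- sz[p] + sz[v]
    }
  }
  paste(sz, s1, s2)
}

#' Majority-rule consensus of a posterior tree sample
#'
#' Returns the tree containing exactly the clades whose frequency in the
#' sample strictly exceeds `threshold` (default 0.5, the majority rule);
#' with a strict majority the retained clades are guaranteed pairwise
#' compatible, and branching orders that do not reach the threshold appear
#' as multifurcations. Clade support values (sample frequencies) are
#' recorded per internal node. Node times are set to 0; use
#' [annotate_clade_times] (or [consensus_from_sample]) to map mean posterior
#' coalescence times onto the consensus.
#'
#' @param trees a `tree_sample` or list of `gene_tree`s sharing one leaf
#'   set (matched by leaf labels).
#' @param threshold support fraction a clade must strictly exceed to be
#'   retained; must be at least 0.5.
#' @return an object of class `consensus_tree`: list with `tree` (a
#'   `gene_tree`, times initially 0), `support` (per-node vector, `NA` for
#'   leaves, 1 for the root) and `clades` (leaf sets per internal node).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "tree_sample")) trees <- trees$trees
  if (!length(trees)) stop("need at least one tree")
  if (threshold < 0.5) stop("threshold must be at least 0.5")
  n <- trees[[1L]]$n_leaf
  ref_labels <- trees[[1L]]$labels
  hw <- clade_hash_weights(n)
  B <- length(trees)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  first_seen <- new.env(hash = TRUE, parent = emptyenv())
  time_sum <- new.env(hash = TRUE, parent = emptyenv())
  root_times <- numeric(B)
  for (i in seq_len(B)) {
    tr <- trees[[i]]
    if (!identical(tr$labels, ref_labels)) {
      if (!setequal(tr$labels, ref_labels))
        stop(sprintf("tree %d has a different leaf set", i))
      ## permute hash weights so equal labels map to equal weights
      perm <- match(tr$labels, ref_labels)
      hw_i <- list(h1 = hw$h1[perm], h2 = hw$h2[perm])
    } else hw_i <- hw
    sig <- clade_signatures(tr, hw_i)
    root <- tree_root(tr)
    root_times[i] <- tr$time[root]
    internal <- setdiff(seq_along(tr$parent), seq_len(tr$n_leaf))
    internal <- setdiff(internal, root)
    for (v in internal) {
      key <- sig[v]
      cnt <- counts[[key]]
      if (is.null(cnt)) {
        counts[[key]] <- 1L
        time_sum[[key]] <- tr$time[v]
        first_seen[[key]] <- c(i, v)
      } else {
        counts[[key]] <- cnt + 1L
        time_sum[[key]] <- time_sum[[key]] + tr$time[v]
      }
    }
  }
  keys <- ls(counts)
  keep <- keys[vapply(keys, function(k) counts[[k]] / B > threshold, TRUE)]
  ## recover leaf sets of retained clades from their first occurrence
  need <- vapply(keep, function(k) first_seen[[k]][1L], 0)
  clade_sets <- vector("list", length(keep))
  for (ti in unique(need)) {
    cl <- tree_clades(trees[[ti]])
    perm <- match(trees[[ti]]$labels, ref_labels)
    for (j in which(need == ti)) {
      v <- first_seen[[keep[j]]][2L]
      clade_sets[[j]] <- sort(perm[cl[[v]]])
    }
  }
  supports <- vapply(keep, function(k) counts[[k]] / B, 0)
  mean_times <- vapply(keep, function(k) time_sum[[k]] / counts[[k]], 0)
  ## assemble: root first, then retained clades by decreasing size
  o <- order(-lengths(clade_sets))
  clade_sets <- clade_sets[o]
  supports <- supports[o]
  mean_times <- mean_times[o]
  K <- length(clade_sets) + 1L
  parent <- integer(n + K)
  current <- rep.int(n + 1L, n)
  if (K > 1L) for (i in 2L:K) {
    set <- clade_sets[[i - 1L]]
    parent[n + i] <- current[set[1L]]
    current[set] <- n + i
  }
  parent[seq_len(n)] <- current
  parent[n + 1L] <- 0L
  tree <- gene_tree(parent, numeric(n + K), ref_labels)
  support <- c(rep(NA_real_, n), 1, supports)
  cons <- structure(list(tree = tree, support = support,
                         clades = c(list(seq_len(n)), clade_sets),
                         mean_times = c(mean(root_times), mean_times),
                         hash_weights = hw),
                    class = "consensus_tree")
  cons
}

#' Map mean posterior coalescence times onto a consensus tree
#'
#' Each retained clade's time becomes the arithmetic mean, over the sampled
#' trees that contain the clade, of that clade's MRCA node time; the root
#' clade's time is the mean root time over all trees. Because the means are
#' taken over different tree subsets a child clade's mean can exceed its
#' parent's; such violations are repaired top-down by clamping the child to
#' its parent's time, preserving ultrametric TMRCA queries.
#'
#' @param consensus a `consensus_tree` from [majority_consensus].
#' @param trees the same tree sample the consensus was built from.
#' @return the `consensus_tree` with node times filled in.
#' @export
annotate_clade_times <- function(consensus, trees) {
  if (inherits(trees, "tree_sample")) trees <- trees$trees
  stopifnot(inherits(consensus, "consensus_tree"))
  ctree <- consensus$tree
  n <- ctree$n_leaf
  ref_labels <- ctree$labels
  hw <- consensus$hash_weights
  ## signature of every consensus clade
  csig <- clade_signatures(ctree, hw)
  int_ids <- (n + 1L):length(ctree$parent)
  want <- new.env(hash = TRUE, parent = emptyenv())
  for (v in int_ids) want[[csig[v]]] <- v
  t_sum <- numeric(length(ctree$parent))
  t_cnt <- numeric(length(ctree$parent))
  root_sum <- 0
  for (tr in trees) {
    perm_ok <- identical(tr$labels, ref_labels)
    hw_i <- if (perm_ok) hw else {
      perm <- match(tr$labels, ref_labels)
      list(h1 = hw$h1[perm], h2 = hw$h2[perm])
    }
    sig <- clade_signatures(tr, hw_i)
    root <- tree_root(tr)
    root_sum <- root_sum + tr$time[root]
    for (v in setdiff(seq_along(tr$parent), seq_len(tr$n_leaf))) {
      hit <- want[[sig[v]]]
      if (!is.null(hit)) {
        t_sum[hit] <- t_sum[hit] + tr$time[v]
        t_cnt[hit] <- t_cnt[hit] + 1
      }
    }
  }
  time <- numeric(length(ctree$parent))
  time[int_ids] <- ifelse(t_cnt[int_ids] > 0, t_sum[int_ids] / t_cnt[int_ids], 0)
  time[n + 1L] <- root_sum / length(trees)
  ## top-down monotonicity repair: child mean must not exceed parent mean
  o <- order(-lengths(consensus$clades))
  for (i in o) {
    v <- n + i
    p <- ctree$parent[v]
    if (p > 0L && time[v] > time[p]) time[v] <- time[p]
  }
  consensus$tree$time <- time
  consensus$mean_times <- time[int_ids]
  consensus
}

#' Build and time-annotate a majority-rule consensus in one call
#'
#' @inheritParams majority_consensus
#' @return an annotated `consensus_tree`.
#' @export
consensus_from_sample <- function(trees, threshold = 0.5) {
  annotate_clade_times(majority_consensus(trees, threshold), trees)
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf(paste0("consensus_tree: %d leaves, %d retained clades ",
                     "(root time %.4g)\n"),
              x$tree$n_leaf, length(x$clades) - 1L,
              x$tree$time[x$tree$n_leaf + 1L]))
  invisible(x)
}

#' Posterior mean coalescence time of two leaves on a consensus tree
#'
#' Looks up the smallest retained clade containing both leaves and returns
#' its annotated mean posterior time (the TMRCA under the consensus).
#'
#' @param consensus an annotated `consensus_tree`.
#' @param leaf_a,leaf_b leaf labels (or 1-based leaf indices).
#' @return the mean posterior coalescence time (internal units).
#' @export
coalescence_time <- function(consensus, leaf_a, leaf_b) {
  stopifnot(inherits(consensus, "consensus_tree"))
  tr <- consensus$tree
  to_idx <- function(x) {
    if (is.character(x)) {
      i <- match(x, tr$labels)
      if (is.na(i)) stop("unknown leaf: ", x)
      i
    } else {
      if (x < 1 || x > tr$n_leaf) stop("unknown leaf index: ", x)
      as.integer(x)
    }
  }
  a <- to_idx(leaf_a); b <- to_idx(leaf_b)
  if (a == b) return(0)
  anc <- integer(0)
  v <- a
  while (v > 0L) { anc <- c(anc, v); v <- tr$parent[v] }
  v <- b
  while (!(v %in% anc)) v <- tr$parent[v]
  tr$time[v]
}
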