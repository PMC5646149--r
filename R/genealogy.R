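#' Pairwise four-gamete compatibility test
#'
#' Two biallelic sites are incompatible with a single genealogical tree
#' (under infinite sites, without recurrent mutation) exactly when all four
#' gametes 00, 01, 10 and 11 occur across the pair of columns.
#'
#' @param col_a,col_b binary vectors of equal length (one entry per
#'   haplotype).
#' @return `FALSE` iff all four gametes occur, `TRUE` otherwise.
#' @export
four_gamete_compatible <- function(col_a, col_b) {
  if (length(col_a) != length(col_b))
    stop("columns must have equal length")
  if (length(col_a) < 2) stop("need at least 2 haplotypes")
  g <- unique(col_a * 2L + col_b)
  length(g) < 4L
}

## index pairs of incompatible columns; NULL when fully compatible
find_incompatible_pair <- function(mat) {
  S <- ncol(mat)
  if (S < 2) return(NULL)
  for (i in seq_len(S - 1L)) {
    for (j in (i + 1L):S) {
      if (!four_gamete_compatible(mat[, i], mat[, j])) return(c(i, j))
    }
  }
  NULL
}

#' Build the perfect phylogeny of a compatible binary matrix
#'
#' Under the infinite-sites model without recombination, the distinct
#' derived-carrier sets of a pairwise four-gamete-compatible matrix are
#' nested or disjoint and therefore define a unique (possibly
#' multifurcating) rooted topology: one clade per distinct carrier set,
#' multifurcations wherever the columns do not resolve branching order, and
#' identical haplotypes attached as children of the same node. Node times
#' are deliberately unset; the skeleton constrains the tree space explored
#' by [mcmc_sample].
#'
#' @param measured a `haplotype_matrix` (typically restricted to the
#'   measured sites) or a binary matrix.
#' @return an object of class `perfect_phylogeny` with elements `parent`
#'   (leaves `1..n` first, then internal nodes in decreasing clade size,
#'   root at `n+1`), `n_leaf`, `labels`, `col_node` (for every input column
#'   the node id whose clade is the derived-carrier set; `NA` for
#'   monomorphic columns) and `clades` (leaf sets of internal nodes).
#' @export
build_perfect_phylogeny <- function(measured) {
  mat <- if (inherits(measured, "haplotype_matrix")) measured$alleles
         else as.matrix(measured)
  labels <- if (inherits(measured, "haplotype_matrix")) measured$labels
            else rownames(mat)
  n <- nrow(mat)
  if (is.null(labels)) labels <- paste0("h", seq_len(n))
  S <- ncol(mat)
  bad <- find_incompatible_pair(mat)
  if (!is.null(bad))
    stop(sprintf(paste0("matrix is not four-gamete compatible: ",
                        "sites %d and %d show all four gametes"),
                 bad[1L], bad[2L]))
  carriers <- lapply(seq_len(S), function(j) which(mat[, j] == 1L))
  sizes <- lengths(carriers)
  informative <- which(sizes >= 2L & sizes < n)
  keys <- vapply(carriers, function(s) paste(s, collapse = ","), "")
  uniq <- informative[!duplicated(keys[informative])]
  ## sort unique clades by decreasing size; root (all leaves) comes first
  uniq <- uniq[order(-sizes[uniq])]
  clade_sets <- c(list(seq_len(n)), carriers[uniq])
  K <- length(clade_sets)
  node_of_key <- c(stats::setNames(n + 1L + seq_along(uniq), keys[uniq]))
  parent <- integer(n + K)
  ## containment assignment: iterate clades largest-first, track for every
  ## leaf the smallest clade seen so far that contains it
  current <- rep.int(n + 1L, n)
  if (K > 1L) {
    for (i in 2L:K) {
      set <- clade_sets[[i]]
      parent[n + i] <- current[set[1L]]
      current[set] <- n + i
    }
  }
  parent[seq_len(n)] <- current
  parent[n + 1L] <- 0L
  col_node <- rep(NA_integer_, S)
  for (j in seq_len(S)) {
    if (sizes[j] == 1L) col_node[j] <- carriers[[j]]
    else if (sizes[j] >= 2L && sizes[j] < n) col_node[j] <- node_of_key[[keys[j]]]
  }
  structure(list(parent = parent, n_leaf = n, labels = labels,
                 col_node = col_node, clades = clade_sets),
            class = "perfect_phylogeny")
}

#' @export
print.perfect_phylogeny <- function(x, ...) {
  cat(sprintf("perfect_phylogeny: %d leaves, %d clades\n",
              x$n_leaf, length(x$clades)))
  invisible(x)
}

#' Priors for genealogy inference
#'
#' @param theta_lower,theta_upper bounds of the uniform prior on the scaled
#'   mutation rate theta (defaults uniform(0, 100)).
#' @param growth_shape,growth_rate shape and rate of the gamma prior on the
#'   exponential growth rate alpha (per generation, as a fraction). With
#'   `growth_rate = NULL` the rate is derived at run time as
#'   `growth_shape / alpha_scenario` so that the prior mean matches the
#'   simulated growth rate (e.g. shape 2 with rate 80 for 2.5\% growth).
#' @param dirichlet_concentration concentration of the symmetric Dirichlet
#'   prior on subpopulation size proportions (structure mode).
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(theta_lower = 0, theta_upper = 100,
                         growth_shape = 2, growth_rate = NULL,
                         dirichlet_concentration = 2) {
  if (theta_lower < 0 || theta_lower >= theta_upper)
    stop("theta prior needs 0 <= lower < upper")
  if (growth_shape <= 0 || (!is.null(growth_rate) && growth_rate <= 0))
    stop("gamma prior parameters must be positive")
  structure(list(theta_lower = theta_lower, theta_upper = theta_upper,
                 growth_shape = growth_shape, growth_rate = growth_rate,
                 dirichlet_concentration = dirichlet_concentration),
            class = "prior_config")
}

## ---- coalescent prior density over node times --------------------------

## Cumulative inverse-relative-size integral in internal units, vectorized
## over tau (internal units), for one deme holding `share` of N_e.
cum_inv_size_units <- function(tau, two_ne, alpha, t_on_gen, share = 1) {
  t <- tau * two_ne
  if (alpha == 0) return(tau / share)
  out <- (exp(alpha * pmin(t, t_on_gen)) - 1) / alpha +
    pmax(t - t_on_gen, 0) * exp(alpha * t_on_gen)
  out / (two_ne * share)
}

## log inverse relative size at tau (hazard multiplier), vectorized
log_inv_size_units <- function(tau, two_ne, alpha, t_on_gen) {
  alpha * pmin(tau * two_ne, t_on_gen)
}

## Core ranked-times log density for panmictic modes. ts: sorted event
## times; dc: lineage decrement per event (1 for binary).
log_prior_panmictic <- function(ts, dc, n, two_ne, alpha, t_on_gen) {
  k_before <- n - c(0, cumsum(dc))[seq_along(ts)]
  ck2 <- k_before * (k_before - 1) / 2
  G <- cum_inv_size_units(c(0, ts), two_ne, alpha, t_on_gen)
  sum(log(ck2)) + sum(log_inv_size_units(ts, two_ne, alpha, t_on_gen)) -
    sum(ck2 * diff(G))
}

## Structured log density over a *labelled* binary tree: within-deme pair
## rate 1/(w_d * nu(t)) before the split, panmictic rate 1 afterwards.
## ts sorted event times; ev_deme: deme of each event's merged clade
## (0 = spans demes); n_d: lineages sampled per deme; tau_split in units.
log_prior_structured <- function(ts, ev_deme, n_d, w, tau_split,
                                 two_ne, alpha, t_on_gen) {
  below <- ts < tau_split
  if (any(ev_deme[below] == 0L)) return(-Inf)
  beta <- length(n_d)
  acc <- 0
  for (d in seq_len(beta)) {
    td <- ts[below & ev_deme == d]
    k <- n_d[d] - c(0L, seq_along(td))
    bounds <- c(0, td, tau_split)
    ck2 <- k * (k - 1) / 2
    G <- cum_inv_size_units(bounds, two_ne, alpha, t_on_gen, share = w[d])
    acc <- acc - sum(ck2 * diff(G)) -
      length(td) * log(w[d]) +
      sum(log_inv_size_units(td, two_ne, alpha, t_on_gen))
  }
  ## ancestral panmictic phase of constant size N_e (pair rate 1)
  ta <- ts[!below]
  k_split <- sum(n_d) - sum(below)
  if (k_split != length(ta) + 1L) return(-Inf)  # tree must finish above split
  if (length(ta)) {
    k <- k_split - (seq_along(ta) - 1L)
    acc <- acc - sum((k * (k - 1) / 2) * diff(c(tau_split, ta)))
  }
  acc
}

#' Coalescent log prior density of a genealogy's node times
#'
#' Density of the coalescence times of an ultrametric tree under the
#' (possibly growth-rescaled, possibly structured) coalescent, in internal
#' units of 2*N_e generations. For constant size and k extant lineages the
#' waiting time to the next coalescence is Exponential(k(k-1)/2), and each
#' event contributes `log(k(k-1)/2)` plus the exponential survival terms
#' (ranked-times convention). In structure mode the density is over the
#' labelled tree: a coalescence joining lineages of subpopulation d before
#' the split has pair rate `1/w_d`, a cross-subpopulation coalescence before
#' the split has density zero, and all lineages coalesce panmictically at
#' pair rate 1 after the (backward) merge.
#'
#' @param tree a `gene_tree`; in structure mode its `leaf_deme` (or the
#'   `leaf_deme` argument) must assign every leaf to a subpopulation.
#' @param demography a [demography_model]; supplies N_e, growth onset,
#'   split time and the number of subpopulations.
#' @param mode one of "basic", "growth", "structure", "growth-structure".
#' @param alpha growth rate used in growth modes (defaults to the
#'   demography's `growth_rate_alpha`).
#' @param w subpopulation size proportions (defaults to equal shares).
#' @param leaf_deme optional per-leaf deme assignment overriding the tree's.
#' @return the log density (can be `-Inf`).
#' @export
coalescent_log_prior <- function(tree, demography = demography_model(),
                                 mode = c("basic", "growth", "structure",
                                          "growth-structure"),
                                 alpha = NULL, w = NULL, leaf_deme = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "gene_tree"))
  d <- demography
  two_ne <- 2 * d$n_e
  use_growth <- mode %in% c("growth", "growth-structure")
  a <- if (use_growth) (if (is.null(alpha)) d$growth_rate_alpha else alpha)
       else 0
  t_on <- if (use_growth) d$growth_onset_generations else 0
  n <- tree$n_leaf
  int_ids <- setdiff(seq_along(tree$parent), seq_len(n))
  kids <- tabulate(tree$parent, nbins = length(tree$parent))
  ord <- order(tree$time[int_ids], method = "radix")
  ts <- tree$time[int_ids][ord]
  dc <- (kids[int_ids] - 1L)[ord]
  if (mode %in% c("basic", "growth"))
    return(log_prior_panmictic(ts, dc, n, two_ne, a, t_on))
  deme <- if (!is.null(leaf_deme)) leaf_deme else tree$leaf_deme
  if (is.null(deme)) stop("structure mode needs a leaf_deme assignment")
  beta <- d$n_subpops_beta
  if (is.null(w)) w <- rep(1 / beta, beta)
  node_deme <- node_demes(tree$parent, n, deme)
  ev_deme <- node_deme[int_ids][ord]
  tau_split <- generations_to_units(d$split_time_generations, d$n_e)
  if (any(dc != 1L)) stop("structure-mode prior requires a binary tree")
  log_prior_structured(ts, ev_deme, tabulate(deme, beta), w, tau_split,
                       two_ne, a, t_on)
}

## deme label of every node: leaves as given, internal nodes the common
## deme of their children or 0 when the clade spans demes
node_demes <- function(parent, n_leaf, leaf_deme) {
  m <- length(parent)
  deme <- integer(m)
  deme[seq_len(n_leaf)] <- leaf_deme
  ## postorder by repeated passes is wasteful; walk nodes in an order where
  ## children precede parents using times is unavailable here, so do a
  ## simple iterative resolution
  remaining <- setdiff(seq_len(m), seq_len(n_leaf))
  done <- c(rep(TRUE, n_leaf), rep(FALSE, m - n_leaf))
  while (length(remaining)) {
    progressed <- FALSE
    keep <- logical(length(remaining))
    for (i in seq_along(remaining)) {
      v <- remaining[i]
      ch <- which(parent == v)
      if (all(done[ch])) {
        dd <- unique(deme[ch])
        deme[v] <- if (length(dd) == 1L && dd != 0L) dd else 0L
        done[v] <- TRUE
        progressed <- TRUE
      } else keep[i] <- TRUE
    }
    remaining <- remaining[keep]
    if (!progressed) stop("cyclic parent structure")
  }
  deme
}

#' Infinite-sites log likelihood of a haplotype matrix given a genealogy
#'
#' Each segregating site is generated by a single mutation falling on one
#' branch with probability proportional to branch length, with the total
#' mutation count Poisson with mean theta * T / 2 (T the total tree length
#' in internal units):
#' `sum_sites log(b_site / T) + S log(theta T / 2) - theta T / 2 - log(S!)`,
#' where `b_site` is the length of the unique branch whose leaf set equals
#' the site's derived-carrier set. Data incompatible with the tree have
#' likelihood zero (`-Inf`).
#'
#' @param tree a `gene_tree`.
#' @param measured a `haplotype_matrix` or binary matrix whose rows align
#'   with the tree's leaves (matched by label when both are labelled).
#' @param theta scaled mutation rate (> 0).
#' @return the log likelihood.
#' @export
infinite_sites_loglik <- function(tree, measured, theta) {
  stopifnot(inherits(tree, "gene_tree"), theta >= 0)
  mat <- if (inherits(measured, "haplotype_matrix")) measured$alleles
         else as.matrix(measured)
  if (!is.null(rownames(mat)) && !is.null(tree$labels) &&
      all(tree$labels %in% rownames(mat)))
    mat <- mat[tree$labels, , drop = FALSE]
  if (nrow(mat) != tree$n_leaf)
    stop("matrix rows must match the tree's leaves")
  S <- ncol(mat)
  clades <- tree_clades(tree)
  keys <- vapply(clades, function(s) paste(s, collapse = ","), "")
  node_of <- stats::setNames(seq_along(keys), keys)
  b <- tree_branch_lengths(tree)
  T_tot <- sum(b, na.rm = TRUE)
  if (S == 0L) return(-theta * T_tot / 2)
  acc <- 0
  root <- tree_root(tree)
  for (j in seq_len(S)) {
    carriers <- which(mat[, j] == 1L)
    node <- node_of[paste(carriers, collapse = ",")]
    if (is.na(node) || node == root) return(-Inf)
    acc <- acc + log(b[node] / T_tot)
  }
  if (theta == 0) return(-Inf)
  acc + S * log(theta * T_tot / 2) - theta * T_tot / 2 - lfactorial(S)
}
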