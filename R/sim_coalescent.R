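#' Sample a gene genealogy under the (extended) coalescent
#'
#' Draws an ultrametric binary genealogy of `n` haplotypes from the Kingman
#' coalescent, with time-rescaling for exponential growth and a structured
#' phase for a clean population split. Backward in time, lineages sampled in
#' different subpopulations cannot coalesce before the split; at the split
#' all residual lineages merge into one panmictic ancestral population of
#' size `n_e`. Node times are returned in internal coalescent units of
#' 2*N_e generations. Randomness is drawn from R's global RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n sample size (number of haplotypes, >= 2).
#' @param demography a [demography_model]; the default is the constant-size
#'   basic coalescent with N_e = 10,000.
#' @return a `gene_tree` with leaf labels `"h1".."hn"`; under structure the
#'   tree carries a `leaf_deme` assignment.
#' @export
sample_genealogy <- function(n, demography = demography_model()) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("n must be a single integer >= 2")
  n <- as.integer(n)
  stopifnot(inherits(demography, "demography_model"))
  d <- demography
  two_ne <- 2 * d$n_e
  beta <- d$n_subpops_beta

  parent <- integer(2L * n - 1L)
  time <- numeric(2L * n - 1L)
  nxt <- n + 1L

  if (beta == 1L) {
    active <- seq_len(n)
    t_cur <- 0
    while (length(active) > 1L) {
      k <- length(active)
      ## waiting time by inversion of the integrated hazard
      e <- stats::rexp(1L)
      target_gen <- e * two_ne / choose(k, 2)
      t_cur <- invert_inverse_size(t_cur, target_gen, d$growth_rate_alpha,
                                   d$growth_onset_generations)
      pair <- sample.int(k, 2L)
      parent[active[pair]] <- nxt
      time[nxt] <- t_cur / two_ne
      active <- c(active[-pair], nxt)
      nxt <- nxt + 1L
    }
    leaf_deme <- NULL
  } else {
    counts <- d$subpop_hap_counts
    if (is.null(counts)) {
      if (n %% beta != 0L)
        stop("n must split evenly over subpopulations or ",
             "subpop_hap_counts must be given")
      counts <- rep(n %/% beta, beta)
    }
    if (sum(counts) != n)
      stop("subpop_hap_counts must sum to the total sample size")
    leaf_deme <- rep(seq_len(beta), counts)
    share <- 1 / beta  # equal deme sizes summing to N_e at sampling time
    t_split <- d$split_time_generations
    active <- vector("list", beta)
    pos <- 0L
    for (b in seq_len(beta)) {
      active[[b]] <- pos + seq_len(counts[b])
      pos <- pos + counts[b]
    }
    ## within-deme phase, truncated at the split
    for (b in seq_len(beta)) {
      t_cur <- 0
      while (length(active[[b]]) > 1L) {
        k <- length(active[[b]])
        e <- stats::rexp(1L)
        target_gen <- e * two_ne / choose(k, 2)
        t_new <- invert_inverse_size(t_cur, target_gen, d$growth_rate_alpha,
                                     d$growth_onset_generations, share)
        if (t_new >= t_split) break
        t_cur <- t_new
        pair <- sample.int(k, 2L)
        parent[active[[b]][pair]] <- nxt
        time[nxt] <- t_cur / two_ne
        active[[b]] <- c(active[[b]][-pair], nxt)
        nxt <- nxt + 1L
      }
    }
    ## panmictic ancestral phase of constant size N_e
    pool <- unlist(active, use.names = FALSE)
    t_cur <- t_split
    while (length(pool) > 1L) {
      k <- length(pool)
      t_cur <- t_cur + stats::rexp(1L) * two_ne / choose(k, 2)
      pair <- sample.int(k, 2L)
      parent[pool[pair]] <- nxt
      time[nxt] <- t_cur / two_ne
      pool <- c(pool[-pair], nxt)
      nxt <- nxt + 1L
    }
  }
  gene_tree(parent, time, labels = paste0("h", seq_len(n)),
            leaf_deme = leaf_deme)
}

#' Haplotype matrix
#'
#' Binary haplotype-by-site matrix: rows are haplotypes, columns are
#' polymorphic sites, entries are 0 (ancestral) / 1 (derived). Column
#' positions are 1-based base-pair coordinates within the simulated segment,
#' strictly increasing.
#'
#' @param alleles binary integer matrix (haplotypes x sites).
#' @param positions integer vector of bp positions, one per column.
#' @param labels haplotype ids (row names).
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, labels = rownames(alleles)) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(labels)) labels <- paste0("h", seq_len(nrow(alleles)))
  if (length(positions) != ncol(alleles))
    stop("one position per site required")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (any(alleles != 0L & alleles != 1L))
    stop("alleles must be 0/1")
  rownames(alleles) <- labels
  structure(list(alleles = alleles, positions = as.integer(positions),
                 labels = labels),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d sites (%d-%d bp)\n",
              nrow(x$alleles), ncol(x$alleles),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Restrict a haplotype matrix to a subset of sites (columns)
#'
#' @param haps a `haplotype_matrix`.
#' @param sites integer vector of site indices to keep.
#' @return a `haplotype_matrix` over the selected sites.
#' @export
subset_sites <- function(haps, sites) {
  haplotype_matrix(haps$alleles[, sites, drop = FALSE],
                   haps$positions[sites], haps$labels)
}

#' Restrict a haplotype matrix to a subset of haplotypes (rows)
#'
#' @param haps a `haplotype_matrix`.
#' @param rows integer vector of haplotype indices to keep.
#' @return a `haplotype_matrix` over the selected haplotypes.
#' @export
subset_haplotypes <- function(haps, rows) {
  haplotype_matrix(haps$alleles[rows, , drop = FALSE],
                   haps$positions, haps$labels[rows])
}

#' Overlay infinite-sites mutations on a genealogy
#'
#' Places mutations on branches chosen with probability proportional to
#' branch length; the derived allele at a site is carried by exactly the
#' leaves below the mutated branch, so every column is polymorphic and maps
#' to one branch of the generating tree. With `n_sites` given, exactly that
#' many segregating sites are produced (fixed-S conditioning); with
#' `n_sites = NULL` and `theta` given, the number of sites is Poisson with
#' mean `theta * T_total / 2`.
#'
#' @param tree a `gene_tree` with >= 2 leaves.
#' @param n_sites number of segregating sites S, or `NULL` to draw S from
#'   the Poisson mutation model.
#' @param seq_length_bp segment length; positions are drawn uniformly
#'   without replacement from `1..seq_length_bp` and sorted.
#' @param theta scaled mutation rate, used only when `n_sites` is `NULL`.
#' @return a `haplotype_matrix` over the tree's leaves.
#' @export
overlay_mutations <- function(tree, n_sites = 100L, seq_length_bp = 20000L,
                              theta = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  if (tree$n_leaf < 2) stop("tree needs at least 2 leaves")
  b <- tree_branch_lengths(tree)
  b[is.na(b)] <- 0
  total <- sum(b)
  if (is.null(n_sites)) {
    if (is.null(theta)) stop("give either n_sites or theta")
    n_sites <- stats::rpois(1L, theta * total / 2)
  }
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L)
    stop("at least one segregating site is required (S >= 1)")
  if (n_sites > seq_length_bp)
    stop("cannot place ", n_sites, " sites on ", seq_length_bp, " bp")
  branch <- sample.int(length(b), n_sites, replace = TRUE, prob = b)
  clades <- tree_clades(tree)
  n <- tree$n_leaf
  alleles <- matrix(0L, n, n_sites)
  for (j in seq_len(n_sites)) alleles[clades[[branch[j]]], j] <- 1L
  positions <- sort(sample.int(seq_length_bp, n_sites))
  ## order columns by position (positions already sorted; branches random)
  haplotype_matrix(alleles, positions, labels = tree$labels)
}

#' Cohort: study/reference split, diploid pairing, measured/masked sites
#'
#' Randomly assigns haplotypes to the study population and the external
#' reference panel, pairs haplotypes into diploid individuals within each
#' partition, and selects the directly measured sites; all remaining sites
#' are masked and later imputed. The full simulated matrix is kept as the
#' held-out truth.
#'
#' @param haps a `haplotype_matrix` of all simulated haplotypes.
#' @param config a [sim_config]; `study_fraction` and `measured_fraction`
#'   control the split. The site selection consumes the current RNG stream
#'   (seed externally for the two-seed design of the scenario runner).
#' @param measured optional preselected measured site indices, bypassing
#'   [choose_measured_sites].
#' @param leaf_deme optional per-haplotype subpopulation labels carried
#'   through from a structured simulation.
#' @return an object of class `cohort` with elements `study`, `reference`
#'   (haplotype indices), `study_pairs`, `ref_pairs` (two-column matrices of
#'   haplotype indices, one row per diploid individual), `measured`,
#'   `masked` (site indices) and `haps` (the truth matrix).
#' @export
make_cohort <- function(haps, config = sim_config(), measured = NULL,
                        leaf_deme = NULL) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  n <- nrow(haps$alleles)
  n_study <- round(config$study_fraction * n)
  n_ref <- n - n_study
  if (n_study %% 2L != 0L || n_ref %% 2L != 0L)
    stop(sprintf(paste0("cannot pair haplotypes into diploids: the split ",
                        "%d study + %d reference contains an odd ",
                        "partition"), n_study, n_ref))
  study <- sort(sample.int(n, n_study))
  reference <- setdiff(seq_len(n), study)
  study_pairs <- matrix(sample(study), ncol = 2L, byrow = TRUE)
  ref_pairs <- matrix(sample(reference), ncol = 2L, byrow = TRUE)
  n_sites <- ncol(haps$alleles)
  if (is.null(measured))
    measured <- choose_measured_sites(haps, config$measured_fraction)
  masked <- setdiff(seq_len(n_sites), measured)
  structure(list(study = study, reference = reference,
                 study_pairs = study_pairs, ref_pairs = ref_pairs,
                 measured = sort(measured), masked = masked,
                 haps = haps, leaf_deme = leaf_deme),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("cohort: %d study + %d reference haplotypes, ",
                     "%d measured / %d masked sites\n"),
              length(x$study), length(x$reference),
              length(x$measured), length(x$masked)))
  invisible(x)
}

#' Select the directly measured sites
#'
#' Samples `round(measured_fraction * n_sites)` site indices uniformly
#' without replacement. With `compatible_only = TRUE`, eligibility is first
#' restricted to a maximal pairwise four-gamete-compatible subset found by
#' greedy left-to-right retention (a site is kept if it is compatible with
#' every site already kept), mirroring the exclusion of incompatible sites
#' ahead of genealogy inference on recombined data.
#'
#' @param haps a `haplotype_matrix`.
#' @param measured_fraction fraction of sites to measure (0, 1].
#' @param compatible_only restrict eligibility to a four-gamete-compatible
#'   subset before sampling.
#' @return sorted integer vector of measured site indices.
#' @export
choose_measured_sites <- function(haps, measured_fraction = 0.1,
                                  compatible_only = FALSE) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  n_sites <- ncol(haps$alleles)
  m <- round(measured_fraction * n_sites)
  if (m < 1L) stop("measured_fraction selects no sites")
  eligible <- seq_len(n_sites)
  if (compatible_only) {
    kept <- integer(0)
    for (j in eligible) {
      ok <- all(vapply(kept, function(k) {
        four_gamete_compatible(haps$alleles[, j], haps$alleles[, k])
      }, logical(1L)))
      if (ok) kept <- c(kept, j)
    }
    eligible <- kept
  }
  if (length(eligible) < m)
    stop(sprintf(paste0("need %d measured sites but only %d eligible ",
                        "sites are available"), m, length(eligible)))
  sort(sample(eligible, m))
}

#' Simulate a complete cohort for one scenario replicate
#'
#' Convenience wrapper chaining [sample_genealogy], [overlay_mutations] and
#' [make_cohort] with the two-seed design: `seed_sim` governs the genealogy,
#' mutations, study/reference split and diploid pairing, while `seed_sites`
#' governs the selection of directly measured sites, so the same simulated
#' haplotypes can be re-used across independent site selections.
#'
#' @param config a [sim_config].
#' @param demography a [demography_model].
#' @return a `cohort` whose `tree` attribute holds the generating genealogy.
#' @export
simulate_cohort <- function(config = sim_config(),
                            demography = demography_model()) {
  set.seed(config$seed_sim)
  tree <- sample_genealogy(config$n_haplotypes, demography)
  haps <- overlay_mutations(tree, config$n_sites_S, config$seq_length_bp_L)
  coh_rng <- sample.int(.Machine$integer.max, 1L)
  set.seed(config$seed_sites)
  measured <- choose_measured_sites(haps, config$measured_fraction)
  set.seed(coh_rng)
  coh <- make_cohort(haps, config, measured = measured,
                     leaf_deme = tree$leaf_deme)
  attr(coh, "tree") <- tree
  coh
}
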