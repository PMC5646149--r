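#' Template selection rule
#'
#' Reference haplotypes coalescing with a study haplotype within
#' `delta_generations` generations of the first-coalescing one all serve as
#' imputation templates. The default window of 10 generations corresponds
#' to 0.001 coalescent units of N_e generations (0.0005 internal units)
#' when N_e = 10,000; the window is converted internally via 2 N_e.
#'
#' @param delta_generations co-coalescence window in generations (>= 0).
#' @param n_e diploid effective population size used for the conversion to
#'   internal coalescent units.
#' @return an object of class `template_rule`.
#' @export
template_rule <- function(delta_generations = 10, n_e = 10000) {
  if (delta_generations < 0) stop("delta_generations must be >= 0")
  structure(list(delta_generations = delta_generations, n_e = n_e,
                 delta_units = delta_generations / (2 * n_e)),
            class = "template_rule")
}

#' Find imputation templates for one study haplotype
#'
#' Implements the two-stage rule: (1) if the reference panel contains
#' haplotypes identical to the study haplotype at all directly measured
#' sites, all such matches are the templates and the tree is not consulted;
#' (2) otherwise, with `t*` the smallest mean posterior coalescence time
#' between the study haplotype and any reference haplotype on the consensus
#' tree, every reference haplotype coalescing within `t* + delta` serves as
#' a template.
#'
#' @param study_hap haplotype index (row of the cohort's truth matrix).
#' @param cohort a `cohort`.
#' @param consensus an annotated `consensus_tree` covering all cohort
#'   haplotypes (leaf labels must match the haplotype labels).
#' @param rule a [template_rule].
#' @return integer vector of reference haplotype indices.
#' @export
find_templates <- function(study_hap, cohort, consensus,
                           rule = template_rule()) {
  stopifnot(inherits(cohort, "cohort"))
  if (!length(cohort$reference)) stop("reference panel is empty")
  meas <- cohort$measured
  A <- cohort$haps$alleles
  pat <- A[study_hap, meas]
  refs <- cohort$reference
  same <- refs[colSums(abs(t(A[refs, meas, drop = FALSE]) - pat)) == 0L]
  if (length(same)) return(same)
  lookup <- consensus_leaf_index(cohort, consensus)
  templates_by_tree(lookup$leaf_of_hap[study_hap], lookup, consensus,
                    rule$delta_units)
}

## map cohort haplotype indices to consensus leaf indices (by label) and
## mark which consensus leaves are reference haplotypes
consensus_leaf_index <- function(cohort, consensus) {
  labs <- consensus$tree$labels
  leaf_of_hap <- match(cohort$haps$labels, labs)
  if (anyNA(leaf_of_hap[c(cohort$study, cohort$reference)]))
    stop("consensus tree does not cover all cohort haplotypes")
  is_ref <- logical(length(labs))
  is_ref[leaf_of_hap[cohort$reference]] <- TRUE
  hap_of_leaf <- match(labs, cohort$haps$labels)
  list(leaf_of_hap = leaf_of_hap, is_ref = is_ref,
       hap_of_leaf = hap_of_leaf)
}

## tree-walk template search: ascend from the study leaf, collecting the
## reference leaves that first appear under each ancestor; t* is the time
## of the first ancestor holding any reference, the window extends t*+delta
templates_by_tree <- function(leaf, lookup, consensus, delta_units) {
  tr <- consensus$tree
  n <- tr$n_leaf
  seen <- logical(n)
  seen[leaf] <- TRUE
  out <- integer(0)
  t_star <- NA_real_
  v <- tr$parent[leaf]
  while (v > 0L) {
    members <- consensus$clades[[v - n]]
    new_refs <- members[lookup$is_ref[members] & !seen[members]]
    seen[members] <- TRUE
    t_v <- tr$time[v]
    if (length(new_refs)) {
      if (is.na(t_star)) t_star <- t_v
      if (t_v <= t_star + delta_units + 1e-12)
        out <- c(out, new_refs)
      else break
    } else if (!is.na(t_star) && t_v > t_star + delta_units + 1e-12) break
    v <- tr$parent[v]
  }
  sort(lookup$hap_of_leaf[out])
}

#' Per-site derived-allele probabilities from a template set
#'
#' The probability of the derived allele at each masked site is the
#' fraction of templates carrying it.
#'
#' @param templates integer vector of reference haplotype indices.
#' @param cohort a `cohort`.
#' @return numeric vector of P(allele = 1) over the cohort's masked sites.
#' @export
impute_haplotype <- function(templates, cohort) {
  if (!length(templates)) stop("template set is empty")
  colMeans(cohort$haps$alleles[templates, cohort$masked, drop = FALSE])
}

#' Combine two haplotype imputations into genotype probabilities
#'
#' Treats the two haplotype-level imputations of a diploid individual as
#' independent: P(G=2) = p_a p_b, P(G=0) = (1-p_a)(1-p_b),
#' P(G=1) = 1 - P(0) - P(2). The best guess is the argmax; exact ties are
#' broken towards the genotype with the larger Hardy-Weinberg expected
#' frequency under the reference-panel allele frequency.
#'
#' @param hap_probs_a,hap_probs_b numeric vectors of P(allele = 1) over the
#'   same masked sites.
#' @param ref_freq reference-panel derived-allele frequency at those sites
#'   (used only for tie-breaking).
#' @return list with `probs` (3 x n matrix, rows genotypes 0/1/2) and
#'   `best` (integer vector of best-guess genotypes).
#' @export
impute_individual <- function(hap_probs_a, hap_probs_b,
                              ref_freq = rep(0.5, length(hap_probs_a))) {
  if (length(hap_probs_a) != length(hap_probs_b))
    stop("haplotype probability vectors must cover the same masked sites")
  p0 <- (1 - hap_probs_a) * (1 - hap_probs_b)
  p2 <- hap_probs_a * hap_probs_b
  p1 <- 1 - p0 - p2
  probs <- rbind(`0` = p0, `1` = p1, `2` = p2)
  list(probs = probs, best = best_guess_genotype(probs, ref_freq))
}

## argmax over genotype probabilities with HWE tie-break: among tied
## genotypes prefer the one with larger expected frequency given the
## reference-panel allele frequency
best_guess_genotype <- function(probs, ref_freq) {
  m <- ncol(probs)
  hwe <- rbind((1 - ref_freq)^2, 2 * ref_freq * (1 - ref_freq), ref_freq^2)
  best <- integer(m)
  for (j in seq_len(m)) {
    p <- probs[, j]
    top <- which(p >= max(p) - 1e-12)
    if (length(top) > 1L) top <- top[which.max(hwe[top, j])]
    best[j] <- top - 1L
  }
  best
}

#' Coalescent-based genotype imputation of a whole cohort
#'
#' Runs the template search for every study haplotype (identical study
#' haplotypes share their template set), converts template allele
#' distributions into per-haplotype allele probabilities, and combines the
#' two haplotypes of each study individual into genotype posteriors at all
#' masked sites.
#'
#' @param cohort a `cohort`.
#' @param consensus an annotated `consensus_tree`.
#' @param rule a [template_rule].
#' @return an object of class `genotype_posterior`: list with `probs`
#'   (array individuals x masked sites x 3), `best` (matrix of best-guess
#'   genotypes), `hap_probs` (per study haplotype allele probabilities),
#'   `sites` (masked site indices) and `individuals` (the study pair
#'   matrix).
#' @export
impute_cohort_coalescent <- function(cohort, consensus,
                                     rule = template_rule()) {
  stopifnot(inherits(cohort, "cohort"))
  meas <- cohort$measured
  A <- cohort$haps$alleles
  refs <- cohort$reference
  masked <- cohort$masked
  ref_freq <- colMeans(A[refs, masked, drop = FALSE])
  lookup <- consensus_leaf_index(cohort, consensus)

  ## group study haplotypes by measured pattern: the identical-match path
  ## is pattern-determined, and within a pattern with matches the template
  ## set is shared
  study <- cohort$study
  pat_key <- apply(A[study, meas, drop = FALSE], 1L, paste, collapse = "")
  ref_key <- apply(A[refs, meas, drop = FALSE], 1L, paste, collapse = "")
  hap_probs <- matrix(NA_real_, length(study), length(masked),
                      dimnames = list(cohort$haps$labels[study], NULL))
  for (key in unique(pat_key)) {
    members <- study[pat_key == key]
    same <- refs[ref_key == key]
    if (length(same)) {
      p <- impute_haplotype(same, cohort)
      hap_probs[match(members, study), ] <- matrix(p, length(members),
                                                   length(masked),
                                                   byrow = TRUE)
    } else {
      for (h in members) {
        tpl <- templates_by_tree(lookup$leaf_of_hap[h], lookup, consensus,
                                 rule$delta_units)
        hap_probs[match(h, study), ] <- impute_haplotype(tpl, cohort)
      }
    }
  }

  pairs <- cohort$study_pairs
  n_ind <- nrow(pairs)
  probs <- array(NA_real_, c(n_ind, length(masked), 3L))
  best <- matrix(NA_integer_, n_ind, length(masked))
  for (i in seq_len(n_ind)) {
    pa <- hap_probs[match(pairs[i, 1L], study), ]
    pb <- hap_probs[match(pairs[i, 2L], study), ]
    ind <- impute_individual(pa, pb, ref_freq)
    probs[i, , ] <- t(ind$probs)
    best[i, ] <- ind$best
  }
  structure(list(probs = probs, best = best, hap_probs = hap_probs,
                 sites = masked, individuals = pairs),
            class = "genotype_posterior")
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat(sprintf("genotype_posterior: %d individuals x %d masked sites\n",
              nrow(x$best), ncol(x$best)))
  invisible(x)
}
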