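## shared fixture builders; everything is generated in code

## a fixed four-leaf tree: ((h1,h2):0.5,(h3,h4):0.8):1.2 with cherry times
## 0.5 and 0.8 and root 1.2
fixture_tree4 <- function() {
  gene_tree(parent = c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
            time = c(0, 0, 0, 0, 1.2, 0.5, 0.8),
            labels = paste0("h", 1:4))
}

## empty-matrix haplotype container over n leaves (zero segregating sites)
fixture_empty_haps <- function(n) {
  structure(list(alleles = matrix(integer(0), n, 0),
                 positions = integer(0),
                 labels = paste0("h", seq_len(n))),
            class = "haplotype_matrix")
}

## hand-built perfect-phylogeny cohort: 8 haplotypes, 6 sites; two clades
## {1..4} and {5..8} refined by cherries; every study pattern is present in
## the reference panel. Returns a cohort with 4 study / 4 reference.
fixture_toy_cohort <- function(measured = c(1L, 4L)) {
  ## sites: 1 -> clade {1,2,3,4}; 2 -> {1,2}; 3 -> {3,4};
  ##        4 -> clade {5,6,7,8}; 5 -> {5,6}; 6 -> {7,8}
  carriers <- list(1:4, 1:2, 3:4, 5:8, 5:6, 7:8)
  A <- matrix(0L, 8, 6)
  for (j in seq_along(carriers)) A[carriers[[j]], j] <- 1L
  haps <- haplotype_matrix(A, positions = seq(100, 600, by = 100),
                           labels = paste0("h", 1:8))
  ## study = one haplotype of each cherry, reference = the other
  study <- c(1L, 3L, 5L, 7L)
  reference <- c(2L, 4L, 6L, 8L)
  structure(list(study = study, reference = reference,
                 study_pairs = matrix(study, 2L, 2L, byrow = TRUE),
                 ref_pairs = matrix(reference, 2L, 2L, byrow = TRUE),
                 measured = sort(measured),
                 masked = setdiff(seq_len(6L), measured),
                 haps = haps, leaf_deme = NULL),
            class = "cohort")
}

## wrap a single gene_tree as an annotated consensus (all supports 1)
fixture_consensus_of <- function(tree) {
  consensus_from_sample(list(tree))
}
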