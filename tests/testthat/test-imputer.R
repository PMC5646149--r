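test_that("identical reference matches bypass the tree", {
  coh <- fixture_toy_cohort(measured = c(1L, 4L))
  ## at measured sites 1 & 4, patterns are (1,0) for haps 1..4 and (0,1)
  ## for 5..8: every study hap has two identical references
  cons <- fixture_consensus_of(sample_genealogy(8))  # arbitrary tree
  expect_setequal(find_templates(1L, coh, cons), c(2L, 4L))
  expect_setequal(find_templates(5L, coh, cons), c(6L, 8L))
})

test_that("template windows select first-coalescing references", {
  ## study leaf h1; references h2, h3, h4 with TMRCAs 0.10, 0.50, 0.60
  tr <- gene_tree(c(5L, 5L, 6L, 7L, 6L, 7L, 0L),
                  c(0, 0, 0, 0, 0.10, 0.50, 0.60),
                  paste0("h", 1:4))
  cons <- fixture_consensus_of(tr)
  A <- matrix(c(0L, 1L, 1L, 1L), 4, 1)  # h1 never matches a reference
  coh <- structure(list(study = 1L, reference = 2:4,
                        study_pairs = matrix(c(1L, 1L), 1, 2),
                        ref_pairs = matrix(c(2L, 3L), 1, 2),
                        measured = 1L, masked = integer(0),
                        haps = haplotype_matrix(A, 50, paste0("h", 1:4)),
                        leaf_deme = NULL), class = "cohort")
  ## delta -> 0: only the first-coalescing reference
  expect_identical(find_templates(1L, coh, cons, template_rule(0)),
                   2L)
  ## delta window covering 0.50 but not 0.60 (in generations: units*2Ne)
  rule <- template_rule((0.50 - 0.10) * 2 * 10000, 10000)
  expect_setequal(find_templates(1L, coh, cons, rule), c(2L, 3L))
  ## empty panel errors
  coh_empty <- coh; coh_empty$reference <- integer(0)
  expect_error(find_templates(1L, coh_empty, cons), "empty")
})

test_that("allele probabilities are template frequencies", {
  coh <- fixture_toy_cohort(measured = c(1L, 4L))
  ## masked sites are 2,3,5,6; templates {2,4} disagree at sites 2 and 3
  p <- impute_haplotype(c(2L, 4L), coh)
  expect_equal(unname(p), c(0.5, 0.5, 0, 0))
  p2 <- impute_haplotype(c(2L, 2L, 4L), coh)
  expect_equal(unname(p2[1]), 2 / 3)
  expect_error(impute_haplotype(integer(0), coh), "empty")
})

test_that("genotype combination multiplies independent haplotypes", {
  r <- impute_individual(1, 1)
  expect_equal(unname(r$probs[, 1]), c(0, 0, 1))
  expect_identical(r$best, 2L)
  r <- impute_individual(1, 0)
  expect_equal(unname(r$probs[, 1]), c(0, 1, 0))
  r <- impute_individual(0.5, 0.5)
  expect_equal(unname(r$probs[, 1]), c(0.25, 0.5, 0.25))
  expect_identical(r$best, 1L)
  expect_error(impute_individual(c(0.5, 0.5), 0.5), "same masked sites")
})

test_that("argmax ties break towards the HWE-likelier genotype", {
  ## p_a = 1, p_b = 0.5 gives P = (0, 0.5, 0.5): tie between 1 and 2
  r_common <- impute_individual(1, 0.5, ref_freq = 0.9)
  expect_identical(r_common$best, 2L)   # freq 0.9: hom-derived likelier
  r_rare <- impute_individual(1, 0.5, ref_freq = 0.3)
  expect_identical(r_rare$best, 1L)     # freq 0.3: het likelier
})

test_that("template probabilities ignore template order", {
  coh <- fixture_toy_cohort()
  expect_equal(impute_haplotype(c(2L, 4L), coh),
               impute_haplotype(c(4L, 2L), coh))
})

test_that("a unique full-length donor yields perfect imputation", {
  set.seed(501)
  tr <- sample_genealogy(12)
  h <- overlay_mutations(tr, 20, 2000)
  A <- h$alleles
  ## make reference hap 12 a perfect copy of study hap 1
  A[12, ] <- A[1, ]
  ## de-duplicate every other reference pattern at measured sites so the
  ## donor is the unique identical match
  meas <- 1:5
  for (r in 9:11) if (all(A[r, meas] == A[1, meas])) A[r, meas[1]] <- 1L - A[r, meas[1]]
  h2 <- haplotype_matrix(A, h$positions, h$labels)
  coh <- structure(list(study = 1:8, reference = 9:12,
                        study_pairs = matrix(1:8, 4, 2, byrow = TRUE),
                        ref_pairs = matrix(9:12, 2, 2, byrow = TRUE),
                        measured = meas, masked = 6:20,
                        haps = h2, leaf_deme = NULL), class = "cohort")
  same <- find_templates(1L, coh, fixture_consensus_of(tr))
  expect_identical(same, 12L)
  p <- impute_haplotype(same, coh)
  expect_equal(unname(p), unname(A[1, 6:20]))
})

test_that("end-to-end toy cohort is imputed without error", {
  set.seed(502)
  coh <- fixture_toy_cohort(measured = c(2L, 5L, 6L))
  meas <- subset_sites(coh$haps, coh$measured)
  ts <- mcmc_sample(meas, n_samples = 150, thin = 2)
  cons <- consensus_from_sample(ts)
  post <- impute_cohort_coalescent(coh, cons)
  truth <- coh$haps$alleles[coh$study_pairs[, 1], coh$masked] +
    coh$haps$alleles[coh$study_pairs[, 2], coh$masked]
  ## every study haplotype has an identical-pattern reference carrying the
  ## same masked alleles, so recovery must be exact
  expect_identical(unname(post$best), unname(truth))
})
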