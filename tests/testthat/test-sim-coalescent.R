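test_that("TMRCA matches coalescent closed forms by Monte Carlo", {
  set.seed(101)
  ## E[TMRCA] = 2(1 - 1/n) internal units; n = 2 gives 1
  t2 <- replicate(3000, max(sample_genealogy(2)$time))
  expect_equal(mean(t2), 1, tolerance = 0.06)
  t10 <- replicate(1500, max(sample_genealogy(10)$time))
  expect_equal(mean(t10), 2 * (1 - 1 / 10), tolerance = 0.08)
})

test_that("exponential growth shortens genealogies", {
  set.seed(102)
  d <- demography_model(growth_rate_alpha = 0.05,
                        growth_onset_generations = 200)
  tg <- replicate(400, max(sample_genealogy(10, d)$time))
  t0 <- replicate(400, max(sample_genealogy(10)$time))
  expect_lt(mean(tg), mean(t0))
})

test_that("inter-coalescence intervals are Exponential(k(k-1)/2)", {
  set.seed(103)
  ## first interval of an n = 5 genealogy has rate C(5,2) = 10
  iv <- replicate(2000, {
    tr <- sample_genealogy(5)
    min(tr$time[tr$time > 0])
  })
  ks <- suppressWarnings(stats::ks.test(iv, stats::pexp, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("no between-deme coalescence occurs before the split", {
  set.seed(104)
  d <- demography_model(n_subpops_beta = 3, split_time_generations = 2000,
                        subpop_hap_counts = c(4, 4, 4))
  tau_split <- 2000 / (2 * d$n_e)
  for (r in 1:50) {
    tr <- sample_genealogy(12, d)
    cl <- tree_clades(tr)
    for (v in seq_along(tr$parent)) {
      if (v <= 12) next
      demes <- unique(tr$leaf_deme[cl[[v]]])
      if (length(demes) > 1) expect_gte(tr$time[v], tau_split)
    }
  }
})

test_that("site frequency spectrum follows branch-length expectations", {
  set.seed(105)
  n <- 20
  ## theory: E[# derived-allele-count-i sites] is proportional to 1/i,
  ## up to the fixed-S conditioning which weights each tree by its own
  ## branch-length shares E[b_i / T]. The oracle below computes those
  ## shares by Monte Carlo from the genealogy simulator alone, without
  ## touching the mutation-placement code under test.
  sfs_share <- function(tr) {
    cl <- tree_clades(tr)
    b <- numeric(length(tr$parent))
    nz <- tr$parent > 0L
    b[nz] <- tr$time[tr$parent[nz]] - tr$time[nz]
    out <- numeric(n - 1)
    for (v in which(nz)) {
      i <- length(cl[[v]])
      if (i < n) out[i] <- out[i] + b[v]
    }
    out / sum(b)
  }
  oracle <- rowMeans(replicate(1200, sfs_share(sample_genealogy(n))))
  ## 1/i is a close first-order description of the oracle shares
  p_theory <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  expect_gt(cor(oracle, p_theory), 0.99)
  ## one site per tree keeps the pooled counts exactly multinomial
  ## (several sites per tree would cluster and overdisperse the test)
  counts <- integer(n - 1)
  for (r in 1:2000) {
    tr <- sample_genealogy(n)
    h <- overlay_mutations(tr, 1, 5000)
    counts <- counts + tabulate(colSums(h$alleles), n - 1)
  }
  obs <- c(counts[1:5], sum(counts[6:(n - 1)]))
  expected_p <- c(oracle[1:5], sum(oracle[6:(n - 1)]))
  gof <- stats::chisq.test(obs, p = expected_p / sum(expected_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("mutation overlay yields polymorphic sites mapping to branches", {
  set.seed(106)
  tr <- sample_genealogy(15)
  h <- overlay_mutations(tr, 100, 20000)
  expect_identical(ncol(h$alleles), 100L)
  dac <- colSums(h$alleles)
  expect_true(all(dac >= 1 & dac <= 14))
  expect_true(!is.unsorted(h$positions, strictly = TRUE))
  ## every carrier set equals the leaf set of some branch
  cl <- tree_clades(tr)
  keys <- vapply(cl, function(s) paste(s, collapse = ","), "")
  for (j in seq_len(ncol(h$alleles))) {
    expect_true(paste(which(h$alleles[, j] == 1L), collapse = ",") %in% keys)
  }
  ## two-leaf tree, one site: exactly one carrier
  tr2 <- sample_genealogy(2)
  h2 <- overlay_mutations(tr2, 1, 100)
  expect_identical(sum(h2$alleles), 1L)
})

test_that("simulated matrices are pairwise four-gamete compatible", {
  set.seed(107)
  for (r in 1:5) {
    tr <- sample_genealogy(12)
    h <- overlay_mutations(tr, 25, 20000)
    S <- ncol(h$alleles)
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      expect_true(four_gamete_compatible(h$alleles[, i], h$alleles[, j]))
    }
  }
})

test_that("cohort assembly reproduces the study/reference design", {
  set.seed(108)
  tr <- sample_genealogy(1000)
  h <- overlay_mutations(tr, 100, 20000)
  coh <- make_cohort(h, sim_config())
  expect_length(coh$study, 800L)
  expect_length(coh$reference, 200L)
  expect_setequal(c(coh$study, coh$reference), 1:1000)
  ## pairing covers each partition exactly once
  expect_setequal(as.vector(coh$study_pairs), coh$study)
  expect_setequal(as.vector(coh$ref_pairs), coh$reference)
  expect_length(coh$measured, 10L)
  expect_length(intersect(coh$measured, coh$masked), 0L)
  expect_length(union(coh$measured, coh$masked), 100L)

  tr2 <- sample_genealogy(200)
  h2 <- overlay_mutations(tr2, 100, 20000)
  coh2 <- make_cohort(h2, sim_config(n_haplotypes = 200))
  expect_length(coh2$study, 160L)
  expect_length(coh2$reference, 40L)
})

test_that("cohorts are deterministic given seeds and reject odd splits", {
  cfg <- sim_config(n_haplotypes = 200, seed_sim = 9, seed_sites = 3)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$study, c2$study)
  expect_identical(c1$study_pairs, c2$study_pairs)
  expect_identical(c1$measured, c2$measured)
  expect_identical(c1$haps$alleles, c2$haps$alleles)

  set.seed(1)
  tr <- sample_genealogy(10)
  h <- overlay_mutations(tr, 10, 1000)
  expect_error(make_cohort(h, sim_config(study_fraction = 0.5)),
               "odd partition")
})

test_that("measured-site selection honours fractions and eligibility", {
  set.seed(109)
  tr <- sample_genealogy(30)
  h <- overlay_mutations(tr, 100, 20000)
  m <- choose_measured_sites(h, 0.1)
  expect_length(m, 10L)
  expect_true(!is.unsorted(m, strictly = TRUE))
  ## fraction 1 returns every site; tree data are fully compatible so the
  ## four-gamete restriction must not remove any site
  expect_setequal(choose_measured_sites(h, 1), 1:100)
  expect_setequal(choose_measured_sites(h, 1, compatible_only = TRUE),
                  1:100)
  expect_error(choose_measured_sites(subset_sites(h, 1:5), 1e-9),
               "no sites")
})
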