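test_that("four-gamete test enumerates gametes correctly", {
  expect_false(four_gamete_compatible(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_true(four_gamete_compatible(c(0, 0, 1, 1), c(0, 0, 0, 1)))
  x <- c(0, 1, 1, 0, 1)
  expect_true(four_gamete_compatible(x, x))
  expect_error(four_gamete_compatible(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("perfect phylogeny reflects nesting, stars and incompatibility", {
  ## nested carrier sets {1,2} within {1,2,3} over 4 haplotypes
  m <- cbind(c(1, 1, 0, 0), c(1, 1, 1, 0))
  pp <- build_perfect_phylogeny(m)
  expect_identical(pp$parent[7L], 6L)   # {1,2} nests inside {1,2,3}
  expect_identical(pp$parent[6L], 5L)   # {1,2,3} hangs off the root
  expect_identical(pp$parent[1:4], c(7L, 7L, 6L, 5L))
  expect_identical(pp$col_node, c(7L, 6L))

  ## all-singleton columns give a star
  m2 <- diag(4)
  pp2 <- build_perfect_phylogeny(m2)
  expect_length(pp2$clades, 1L)
  expect_identical(pp2$parent[1:4], rep(5L, 4L))
  expect_identical(pp2$col_node, 1:4)

  ## overlapping but non-nested sets are rejected with the offending pair
  m3 <- cbind(c(1, 1, 0, 0), c(0, 1, 1, 0))
  expect_error(build_perfect_phylogeny(m3), "sites 1 and 2")
})

test_that("coalescent log prior matches closed forms", {
  ## n = 2, T = t: rate-1 exponential, log density -t (log C(2,2) = 0)
  tr2 <- gene_tree(c(3L, 3L, 0L), c(0, 0, 0.7), c("a", "b"))
  expect_equal(coalescent_log_prior(tr2), -0.7)
  ## n = 3 with intervals t1, t2 - t1: log3 - 3 t1 - (t2 - t1)
  t1 <- 0.2; t2 <- 0.9
  tr3 <- gene_tree(c(4L, 4L, 5L, 5L, 0L), c(0, 0, 0, t1, t2),
                   c("a", "b", "c"))
  expect_equal(coalescent_log_prior(tr3),
               log(3) - 3 * t1 - (t2 - t1))
})

test_that("growth prior concentrates on shorter trees", {
  ## same tree, increasing alpha: the density at long times must drop
  tr <- gene_tree(c(3L, 3L, 0L), c(0, 0, 0.5), c("a", "b"))
  d1 <- demography_model(growth_rate_alpha = 0.01,
                         growth_onset_generations = 500)
  d2 <- demography_model(growth_rate_alpha = 0.05,
                         growth_onset_generations = 500)
  lp1 <- coalescent_log_prior(tr, d1, mode = "growth")
  lp2 <- coalescent_log_prior(tr, d2, mode = "growth")
  expect_lt(lp2, lp1)
  ## and prior-predictive mean times shrink with alpha (Monte Carlo)
  set.seed(201)
  m1 <- mean(replicate(300, max(sample_genealogy(6, d1)$time)))
  m2 <- mean(replicate(300, max(sample_genealogy(6, d2)$time)))
  expect_lt(m2, m1)
})

test_that("structured prior forbids early cross-deme coalescence", {
  d <- demography_model(n_subpops_beta = 2, split_time_generations = 2000,
                        subpop_hap_counts = c(2, 2))
  tau <- 2000 / 20000
  ## cherry {1,2} within deme 1, {3,4} within deme 2, root above split
  mk <- function(t_root) gene_tree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                                   c(0, 0, 0, 0, t_root, 0.01, 0.02),
                                   paste0("h", 1:4),
                                   leaf_deme = c(1L, 1L, 2L, 2L))
  expect_true(is.finite(coalescent_log_prior(mk(0.3), d, "structure")))
  expect_identical(coalescent_log_prior(mk(0.05), d, "structure"), -Inf)
})

test_that("infinite-sites likelihood matches a brute-force placement sum", {
  set.seed(202)
  for (r in 1:5) {
    n <- sample(3:5, 1)
    tr <- sample_genealogy(n)
    S <- sample(1:4, 1)
    h <- overlay_mutations(tr, S, 1000)
    theta <- runif(1, 0.5, 5)
    ## oracle: enumerate every assignment of the S sites to branches and
    ## add up Poisson-placement probabilities of those matching the data
    b <- numeric(length(tr$parent))
    nz <- tr$parent > 0L
    b[nz] <- tr$time[tr$parent[nz]] - tr$time[nz]
    Tt <- sum(b)
    cl <- tree_clades(tr)
    total <- 0
    grid <- expand.grid(rep(list(seq_along(b)), S))
    for (g in seq_len(nrow(grid))) {
      br <- as.integer(grid[g, ])
      ok <- all(vapply(seq_len(S), function(j) {
        identical(cl[[br[j]]], unname(which(h$alleles[, j] == 1L)))
      }, TRUE))
      if (ok) total <- total + prod(b[br] / Tt)
    }
    oracle <- log(total) + stats::dpois(S, theta * Tt / 2, log = TRUE)
    expect_equal(infinite_sites_loglik(tr, h, theta), oracle,
                 tolerance = 1e-10)
  }
})

test_that("likelihood degenerates correctly", {
  tr <- gene_tree(c(3L, 3L, 0L), c(0, 0, 1), c("h1", "h2"))
  ## equal external branches: per-site placement factor log(1/2)
  one <- matrix(c(1L, 0L), 2, 1)
  expect_equal(infinite_sites_loglik(tr, one, theta = 2),
               log(1 / 2) + log(2 * 2 / 2) - 2 * 2 / 2 - lfactorial(1))
  ## a column incompatible with the tree has zero likelihood
  tr4 <- fixture_tree4()
  bad <- matrix(c(1L, 0L, 1L, 0L), 4, 1)
  expect_identical(infinite_sites_loglik(tr4, bad, theta = 1), -Inf)
})

test_that("sampler recovers the prior over topologies when data are flat", {
  set.seed(203)
  ts <- mcmc_sample(fixture_empty_haps(3), n_samples = 1200, thin = 3)
  tops <- vapply(ts$trees, function(tr) {
    cl <- tree_clades(tr)
    k <- which(lengths(cl) == 2)[1]
    paste(cl[[k]], collapse = "")
  }, "")
  freq <- table(factor(tops, levels = c("12", "13", "23"))) / length(tops)
  expect_true(all(abs(freq - 1 / 3) < 0.07))
})

test_that("skeleton clades appear in every sampled tree", {
  set.seed(204)
  ## one informative site with carriers {1,2} among 5 haplotypes
  m <- haplotype_matrix(matrix(c(1L, 1L, 0L, 0L, 0L), 5, 1),
                        positions = 10, labels = paste0("h", 1:5))
  ts <- mcmc_sample(m, n_samples = 150, thin = 2)
  for (tr in ts$trees) {
    keys <- vapply(tree_clades(tr), function(s) paste(s, collapse = ","), "")
    expect_true("1,2" %in% keys)
  }
})

test_that("prior-only chains match direct coalescent simulation", {
  set.seed(205)
  ## n = 2: the single coalescence time is Exp(1)
  ts2 <- mcmc_sample(fixture_empty_haps(2), n_samples = 600, thin = 10,
                     prior_only = TRUE)
  t2 <- vapply(ts2$trees, function(tr) tr$time[3], 0)
  expect_gt(suppressWarnings(stats::ks.test(t2, stats::pexp, 1))$p.value,
            0.01)
  ## n = 3: compare the root time against direct simulation (two-sample)
  ts3 <- mcmc_sample(fixture_empty_haps(3), n_samples = 600, thin = 10,
                     prior_only = TRUE)
  t3 <- vapply(ts3$trees, function(tr) max(tr$time), 0)
  ref <- replicate(2000, max(sample_genealogy(3)$time))
  expect_gt(suppressWarnings(stats::ks.test(t3, ref))$p.value, 0.01)
})

test_that("posterior theta increases with the number of segregating sites", {
  set.seed(206)
  tr <- sample_genealogy(12)
  h_lo <- overlay_mutations(tr, 2, 5000)
  h_hi <- overlay_mutations(tr, 25, 5000)
  t_lo <- mcmc_sample(h_lo, n_samples = 300, thin = 3)
  t_hi <- mcmc_sample(h_hi, n_samples = 300, thin = 3)
  expect_lt(mean(t_lo$theta), mean(t_hi$theta))
})

test_that("posterior intervals for theta are roughly calibrated", {
  set.seed(207)
  hits <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    tr <- sample_genealogy(40)
    h <- overlay_mutations(tr, n_sites = NULL, seq_length_bp = 5000,
                           theta = 10)
    if (ncol(h$alleles) < 1) next
    ts <- mcmc_sample(h, n_samples = 250, thin = 3)
    ci <- stats::quantile(ts$theta, c(0.05, 0.95))
    if (ci[1] <= 10 && 10 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
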