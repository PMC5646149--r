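test_that("emission probabilities follow the flip model", {
  expect_equal(emission_prob(2, c(1, 1), 0), 1)
  expect_equal(emission_prob(0, c(1, 1), 0), 0)
  eps <- 0.07
  expect_equal(emission_prob(1, c(1, 0), eps), (1 - eps)^2 + eps^2)
  expect_equal(emission_prob(0, c(1, 0), eps), (1 - eps) * eps)
  expect_equal(emission_prob(NA, c(1, 0), eps), 1)
  expect_error(emission_prob(3, c(1, 0), eps), "genotype")
  ## each column of the emission table is a distribution
  expect_equal(unname(colSums(coalimpute:::emission_table(eps))),
               rep(1, 3))
})

test_that("a single reference haplotype dominates the posterior", {
  H <- matrix(c(1L, 0L, 1L, 1L, 0L), 1, 5)
  G <- c(2L, 0L, NA, NA, NA)
  r <- impute_diploid(G, H, hmm_params(miscopy_epsilon = 1e-9))
  expect_identical(r$best[3:5], c(2L, 2L, 0L))
})

test_that("an individual whose true haplotypes sit in the panel is exact", {
  set.seed(601)
  tr <- sample_genealogy(10)
  h <- overlay_mutations(tr, 12, 2000)
  H <- h$alleles[3:10, ]
  truth <- h$alleles[3, ] + h$alleles[4, ]   # haps 3,4 are in the panel
  G <- truth
  G[c(2, 5, 9)] <- NA
  r <- impute_diploid(G, H, hmm_params(miscopy_epsilon = 1e-6))
  expect_identical(r$best[c(2, 5, 9)], as.integer(truth[c(2, 5, 9)]))
})

test_that("rho = 0 posterior equals an independent pair enumeration", {
  set.seed(602)
  for (rep in 1:4) {
    N <- sample(2:5, 1); L <- sample(3:6, 1)
    H <- matrix(rbinom(N * L, 1, 0.5), N, L)
    eps <- runif(1, 0.01, 0.2)
    G <- rbinom(L, 2, 0.5)
    miss <- sample(L, 2)
    G[miss] <- NA
    ## oracle: loop over ordered pairs, multiply emission_prob per site
    w <- matrix(0, N, N)
    for (i in 1:N) for (j in 1:N) {
      pij <- 1
      for (s in setdiff(1:L, miss))
        pij <- pij * emission_prob(G[s], c(H[i, s], H[j, s]), eps)
      w[i, j] <- pij
    }
    w <- w / sum(w)
    oracle <- sapply(miss, function(s) {
      p <- c(0, 0, 0)
      for (i in 1:N) for (j in 1:N) for (g in 0:2)
        p[g + 1] <- p[g + 1] +
          w[i, j] * emission_prob(g, c(H[i, s], H[j, s]), eps)
      p
    })
    prm <- hmm_params(miscopy_epsilon = eps)
    r_en <- impute_diploid(G, H, prm, method = "enumerate")
    r_fb <- impute_diploid(G, H, prm, method = "forward-backward")
    expect_equal(r_en$probs[, miss], oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(r_fb$probs[, miss], oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("posteriors are proper distributions and order-invariant at rho=0", {
  set.seed(603)
  N <- 6; L <- 8
  H <- matrix(rbinom(N * L, 1, 0.4), N, L)
  G <- rbinom(L, 2, 0.5); G[c(3, 6)] <- NA
  r <- impute_diploid(G, H)
  expect_equal(unname(colSums(r$probs)), rep(1, L), tolerance = 1e-9)
  perm <- sample(L)
  r_p <- impute_diploid(G[perm], H[, perm], hmm_params())
  expect_equal(r_p$probs[, order(perm)], r$probs, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("positive recombination spreads the copying posterior", {
  set.seed(604)
  N <- 4; L <- 6
  H <- matrix(rbinom(N * L, 1, 0.5), N, L)
  G <- H[1, ] + H[2, ]
  G[4] <- NA
  r0 <- impute_diploid(G, H, hmm_params(miscopy_epsilon = 0.01, rho_map = 1e-9),
                       method = "forward-backward")
  r1 <- impute_diploid(G, H, hmm_params(miscopy_epsilon = 0.01, rho_map = 5),
                       method = "forward-backward")
  expect_equal(unname(colSums(r1$probs)), rep(1, L), tolerance = 1e-9)
  ## the rho -> 0 limit of forward-backward matches enumeration
  r_en <- impute_diploid(G, H, hmm_params(miscopy_epsilon = 0.01))
  expect_equal(r0$probs, r_en$probs, tolerance = 1e-6)
})

test_that("cohort-level HMM agrees with per-individual enumeration", {
  set.seed(605)
  cfg <- sim_config(n_haplotypes = 40, n_sites_S = 20,
                    seed_sim = 7, seed_sites = 8)
  coh <- simulate_cohort(cfg)
  post <- impute_cohort_hmm(coh)
  i <- 3L
  pair <- coh$study_pairs[i, ]
  G <- coh$haps$alleles[pair[1], ] + coh$haps$alleles[pair[2], ]
  G[coh$masked] <- NA
  r <- impute_diploid(G, coh$haps$alleles[coh$reference, , drop = FALSE],
                      hmm_params())
  expect_equal(post$probs[i, , ], t(r$probs[, coh$masked]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(post$best[i, ], r$best[coh$masked])
})

test_that("empty panels are rejected", {
  expect_error(impute_diploid(c(1L, NA), matrix(integer(0), 0, 2)),
               "empty")
})
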