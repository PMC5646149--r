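# coalimpute

Coalescent-based genotype imputation within LD-blocks, with a
Li–Stephens haplotype-copying comparator and a full simulation benchmark.

## The problem

Imputation fills in genotypes that a study did not measure by copying
alleles from a phased reference panel. Standard tools are guided by
present-day linkage disequilibrium (LD). Inside an *LD-block* — a segment
with negligible historical recombination — all variants share one gene
genealogy, so the genealogy itself can guide the copying: the reference
haplotype that *first coalesces* with a study haplotype is its closest
available template. `coalimpute` implements this coalescent-based
imputation pipeline for population-genetic simulation studies:

* **Simulation** of haplotype cohorts under the Kingman coalescent
  without recombination, with optional exponential growth and a clean
  population split (`sample_genealogy()`, `overlay_mutations()`,
  `make_cohort()`). The baseline design: 1000 haplotypes, `S = 100`
  polymorphic sites over ~20 kb (`N_e = 10,000`, `mu = 1.25e-8`), 800
  study + 200 reference haplotypes paired into diploids, 10% of sites
  directly measured, the rest masked and imputed.
* **Bayesian genealogy inference** from the measured sites by MCMC over
  binary refinements of the perfect-phylogeny skeleton, with a
  uniform(0, 100) prior on the scaled mutation rate theta and gamma /
  Dirichlet priors for the demographic extensions (`mcmc_sample()`).
* **Majority-rule consensus** trees with mean posterior coalescence
  times mapped onto clades (`consensus_from_sample()`).
* **Template-based imputation**: identical-at-measured-sites reference
  haplotypes if present, otherwise all references coalescing within 10
  generations of the first to coalesce; masked-allele probabilities are
  template allele frequencies (`impute_cohort_coalescent()`).
* **Comparator**: the diploid haplotype-copying hidden Markov model
  `P(G_i | H, mu, rho) = sum_Z P(G_i | Z, mu) P(Z | H, rho)` evaluated at
  recombination rate `rho = 0` (`impute_cohort_hmm()`).
* **Evaluation**: genotype concordance and the chance-corrected
  imputation quality score (IQS), stratified by minor allele frequency,
  with normal-approximation confidence intervals over replicates
  (`evaluate_imputation()`, `run_scenario()`).

See the methods vignette (`vignettes/coalescent-imputation.Rmd`) for the
models, priors, move set and numerical choices.

## Worked example

One replicate of a 200-haplotype scenario (160 study + 40 reference,
100 sites, 10 measured), imputed with both methods and scored against the
held-out truth:

```r
library(coalimpute)
cfg <- scenario_config(n_haplotypes = 200,
                       n_sim_replicates = 1, n_site_selections = 1,
                       n_trees = 200, thin = 4, seed = 7)
res <- run_scenario(cfg)
print(res$table, digits = 3)
#>       method  maf_category n_variants mean_concordance ci_lo ci_hi mean_iqs
#> 1 coalescent           all         90            0.946    NA    NA    0.404
#> 2 coalescent          rare         25            0.986    NA    NA    0.000
#> 3 coalescent low-frequency         17            0.954    NA    NA    0.000
#> 4 coalescent        common         48            0.922    NA    NA    0.740
#> 5        hmm           all         90            0.946    NA    NA    0.405
#> 6        hmm          rare         25            0.986    NA    NA    0.000
#> 7        hmm low-frequency         17            0.954    NA    NA    0.000
#> 8        hmm        common         48            0.922    NA    NA    0.742
```

Reading the output: of the 90 masked variants, 25 are rare (MAF ≤ 0.01),
17 low-frequency and 48 common in the pooled truth. Both methods call
94.6% of masked genotypes correctly overall. Rare variants score high
concordance but zero IQS — calling everyone homozygous-ancestral is
usually right by chance, and the IQS corrects exactly for that — while
common variants carry the informative signal (IQS ≈ 0.74). Confidence
intervals appear once a scenario runs more than one replicate.

The pieces are also available individually:

```r
tree  <- sample_genealogy(200)                      # one genealogy
haps  <- overlay_mutations(tree, 100, 20000)        # 100-site matrix
coh   <- make_cohort(haps, sim_config(n_haplotypes = 200))
ts    <- mcmc_sample(subset_sites(coh$haps, coh$measured),
                     n_samples = 200)
cons  <- consensus_from_sample(ts)
post  <- impute_cohort_coalescent(coh, cons)
evaluate_imputation(coh, post)
```

A thin command-line front end with subcommands `simulate`, `infer-trees`,
`consensus`, `impute`, `baseline`, `evaluate` and `run-scenario` is
installed at `inst/cli/coalimpute.R`; formats are IMPUTE
hap/legend/sample, phased VCF, IMPUTE2-style `.gen` triplets, Newick and
TSV.

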