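---
title: "Coalescent-based genotype imputation within LD-blocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent-based genotype imputation within LD-blocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalimpute)
```

## The problem

Standard genotype imputation copies alleles from a reference panel into a
study individual's unmeasured sites, guided by present-day linkage
disequilibrium (LD). Inside an LD-block — a chromosomal segment with
negligible historical recombination — every variant descends from a single
gene genealogy, so the most natural guide is not current LD but the
genealogy itself: a reference haplotype that coalesces recently with a
study haplotype is, by construction, its closest available template.
`coalimpute` implements this idea end to end for simulated cohorts:

1. **Simulate** haplotype cohorts under the basic Kingman coalescent and
   two demographic extensions (exponential growth; a clean population
   split), with a fixed number `S` of infinite-sites polymorphic sites.
2. **Infer** a posterior sample of gene genealogies from the subset of
   sites treated as directly measured, by MCMC restricted to refinements
   of the perfect-phylogeny skeleton.
3. **Summarise** the sample as a majority-rule consensus tree annotated
   with mean posterior coalescence times.
4. **Impute** each study haplotype's masked alleles from reference
   templates: identical haplotypes at the measured sites if any exist,
   otherwise the reference haplotypes that first coalesce with it.
5. **Benchmark** against a diploid Li–Stephens haplotype-copying HMM
   evaluated at recombination rate 0, scoring both methods by genotype
   concordance and the chance-corrected imputation quality score (IQS).

## Time scales and units

All node times are internally expressed in coalescent units of
`2 N_e` generations (a lineage pair coalesces at rate 1), with
`N_e = 10,000` diploids by default. User-facing thresholds are expressed
in **generations** and converted internally, which sidesteps the ambiguity
between the `N_e`- and `2 N_e`-generation conventions in the literature:
the template co-coalescence window of 10 generations, for instance, is
`0.0005` internal units. Year-based inputs (growth onset 5000 years, split
50,000 years) are converted at 25 years per generation by default
(configurable; 5000 years = 200 generations, 50,000 years = 2000
generations).

## The simulator

`sample_genealogy()` draws binary ultrametric genealogies by inverting the
integrated pair-coalescence hazard, so growth and structure are exact, not
discretised:

* **Constant size** — waiting times are Exponential(k(k−1)/2).
* **Growth** — looking backward from the present, the population size is
  `N(t) = N_e exp(-alpha * min(t, t_onset))`: the present-day size is
  `N_e`, growth started `t_onset` generations ago at per-generation rate
  `alpha`, and the ancestral size is constant at
  `N_e exp(-alpha * t_onset)`.
* **Structure** — `beta` subpopulations of equal present size `N_e / beta`
  evolve independently (no migration) until the split time, looking
  backward; all residual lineages then merge into one panmictic ancestral
  population of size `N_e`.

A note on **growth-rate units**, a place where the design was genuinely
open. Scenario tables in the population-genetics literature often quote
growth coefficients on the coalescent scale used by ms-family simulators
(per `4 N_e` generations) rather than literally per generation. The two
readings differ enormously here: a literal 5% per generation sustained
over 200 generations shrinks the ancestral population below one
individual, making every genealogy a star and every variant a singleton —
demonstrably not the regime in which growth "has little practical effect
on imputation accuracy", which is the regime these scenarios target.
`scenario_config()` therefore interprets its `alpha` on the scaled
convention by default (per-generation rate `alpha / (4 N_e)`), with
`alpha_per_generation = TRUE` as an override; `demography_model()` itself
always takes a literal per-generation rate.

`overlay_mutations()` conditions on a fixed number of segregating sites
(the scenarios fix `S = 100`) rather than a Poisson-theta number: each
site's mutation falls on one branch with probability proportional to
branch length, the derived allele is carried by exactly the leaves below
that branch, and positions are drawn uniformly without replacement from
the 20-kb segment. A Poisson-theta mode (`n_sites = NULL, theta = ...`)
exists for calibration experiments. `make_cohort()` assigns 80% of
haplotypes to the study population, pairs haplotypes at random into
diploids within each partition, and selects 10% of sites as directly
measured; two separate seeds decouple haplotype simulation from site
selection so replicate loops can cross them.

## Genealogy inference

Inference sees only the measured-site submatrix over all study and
reference haplotypes. Under infinite sites without recombination, every
column's derived-carrier set must be a clade, so the distinct carrier sets
form a unique perfect phylogeny (`build_perfect_phylogeny()`), generally
highly multifurcating: with 10 measured sites there are at most 11
distinct haplotype patterns, and most leaves hang in large polytomies.
The MCMC (`mcmc_sample()`) explores exactly the binary refinements of
this skeleton — a restriction that loses no posterior mass and shrinks
the tree space enormously. Identical haplotypes are *not* forced to be
monophyletic: they attach as siblings of the same multifurcation, but any
refinement may interleave them with other lineages, as the coalescent
posterior requires.

The target density is the product of

* the coalescent prior over node times (growth-rescaled where active; in
  structure mode a labelled-tree density with within-subpopulation pair
  rate `1/w_d` before the split, zero density for cross-subpopulation
  coalescences before the split, and panmictic rate 1 afterwards),
* the infinite-sites likelihood
  `sum_j log(b_j / T) + S log(theta T / 2) - theta T / 2 - log(S!)`,
  where `b_j` is the branch subtending site j's carriers and `T` the
  total tree length, and
* the parameter priors: theta ~ uniform(0, 100); in growth mode alpha ~
  Gamma(2, rate) with the rate chosen so the prior mean equals the
  scenario's growth rate; in structure mode subpopulation proportions w ~
  symmetric Dirichlet with concentration 2, and the split time fixed at
  the scenario truth (the data carry almost no information about it at
  these sample sizes, and no prior for it is standard).

Four move families mix the chain: (i) single-node time perturbations,
uniform on the interval between the oldest child and the parent (the root
gets an exponential tail proposal with the matching Hastings term); (ii) a
whole-tree log-scale rescaling; (iii) re-resolution of one multifurcation,
which redraws the merge *pairs* of the block at the current merge times —
this is a draw from the coalescent's conditional topology distribution, so
acceptance is governed by the likelihood alone; and (iv) log-scale random
walks on theta (and alpha). Step sizes adapt towards a 30% acceptance
rate during burn-in only, preserving detailed balance afterwards. The
default chain keeps one tree every 5 sweeps after a burn-in of 25% of the
sampling phase (20% of the total chain).

Why re-resolve topology at *fixed* times? An independence proposal that
also redraws the block's times from a block-local coalescent was
considered and rejected: block-local rates ignore lineages elsewhere in
the tree that coexist in time, so for the large leaf polytomies typical
here the proposal lands far from the conditional density and acceptance
collapses. At fixed times the uniform-pair replay is exactly
prior-conditional, and time mixing is delegated to moves (i)–(ii).

Sampler correctness is validated in the test suite: prior-only chains
reproduce the Exponential interval laws (Kolmogorov–Smirnov), flat data
give the uniform topology distribution at n = 3, the likelihood matches a
brute-force sum over mutation placements on small trees, and a
simulation-based calibration check confirms that 90% posterior intervals
for theta cover the generating value at roughly the nominal rate.

## Consensus and template selection

`majority_consensus()` keeps exactly the clades appearing in strictly more
than half of the sampled trees (threshold 0.5, the strict majority rule,
which guarantees the retained clades are pairwise compatible), and `annotate_clade_times()` maps onto each retained clade
the arithmetic mean of its MRCA time over the trees that contain it, with
the root annotated by the mean root time over all trees. Because means
are taken over different tree subsets, a child clade's mean can slightly
exceed its parent's; such violations are clamped to the parent's time so
TMRCA queries stay ultrametric. Clade bookkeeping uses exact integer
leaf-set fingerprints (sums of fixed 31-bit per-leaf weights, exact in
double precision) so consensus construction is linear in the number of
nodes across the sample.

Templates for a study haplotype are chosen in two stages
(`find_templates()`): all reference haplotypes identical to it at every
measured site, if any exist (the tree is not consulted); otherwise, with
`t*` the smallest consensus TMRCA between the study haplotype and any
reference, every reference within `t* + delta`, where `delta` is 10
generations by default. Masked-allele probabilities are template allele
frequencies; the two haplotypes of an individual combine independently
(`P(G=2) = p_a p_b`, etc.), and best-guess genotypes break exact argmax
ties towards the genotype with the larger Hardy–Weinberg expected
frequency under the reference-panel allele frequency — a deterministic,
frequency-consistent rule.

## The copying-model comparator

`impute_cohort_hmm()` implements the diploid Li–Stephens model
`P(G_i | H, mu, rho) = sum_Z P(G_i | Z, mu) P(Z | H, rho)` with the
recombination rate fixed at 0, so the ordered pair of copied reference
haplotypes is constant along the segment and the posterior is an exact
sum over all N² pairs, weighted by emission products at the measured
genotypes. Each copied allele miscopies independently with probability
epsilon; the default is the standard population-genetic choice
`epsilon = theta~ / (2 (theta~ + N))` with `theta~ = 1 / sum_{i<N} 1/i`.
Positive recombination is implemented (forward–backward over pair states
with factorised switching) and verified against the rho = 0 enumeration,
but the simulation comparisons all run at rho = 0.

An important empirical caveat, documented here because it shapes what the
benchmark can show: at these scenario settings the rho = 0 copying model
is statistically about as accurate as the coalescent method (both near
0.95 mean concordance at the baseline). With at most S+1 distinct
haplotype patterns per genealogy, exact genotype conditioning at the
measured sites concentrates the pair posterior on pattern-compatible
pairs, which largely share masked alleles. Published comparisons in which
an off-the-shelf imputation binary performs substantially worse in this
setting (notably collapsing towards allele-frequency guessing at common
variants) reflect internals of that software — internal re-phasing,
panel-subsetting heuristics, rate flooring — that are outside this
model's definition and outside this package's scope. The package reports
what the written model does.

## Evaluation

Concordance is the fraction of correctly best-guessed genotypes over all
study individuals and all masked variants; the IQS is the per-variant
Cohen's-kappa-style chance correction computed from the 3×3
truth-by-imputed table and averaged over variants. Variants are
stratified by minor allele frequency — rare (MAF ≤ 0.01), low-frequency
(0.01 < MAF ≤ 0.05), common (> 0.05) — with MAF computed from the pooled
truth (study + reference haplotypes), the only definition available
identically to both methods; variants monomorphic in the pooled truth
would be excluded (none arise in fixed-S simulation). Replicate
statistics are summarised as mean ± 1.96 sd/√n, and methods are compared
with equal-variance t and F tests, with documented fallbacks for
zero-variance degenerate inputs.

## Problem sizes and reproducibility

The scenario runner crosses simulation seeds with site-selection seeds,
derived deterministically from one master seed (`child_seed()`), so any
stage can be re-run in isolation. The package's own acceptance runs use
desk-scale versions of the scenarios — 3–4 replicate pairs and 150–250
MCMC trees per configuration instead of 10 × 10 replicates and 1000
trees — sizes at which the Monte-Carlo error of a mean concordance is
about 0.01–0.02 and a full scenario completes in minutes on one CPU.

## What the simulations do and do not show

The generator reproduces the stated study conditions exactly: fixed S,
no recombination inside the block, known ancestral alleles, perfectly
phased haplotypes, and a reference panel drawn from the same population
as the study. Real cohorts violate most of these at once (recurrent
mutation, recombination even in low-recombination regions, phasing error,
panel mismatch), so passing results here demonstrate correctness of the
method under its own assumptions, not field performance. Two further
caveats: the simulated site-frequency spectrum follows the neutral
coalescent (verified against branch-length expectations in the tests),
so published tables whose variant-category counts deviate from neutral
expectations will differ in the "all variants" aggregate purely through
the spectrum; and with a handful of measured sites the genealogy is only
partly identified, so consensus times for weakly supported clades carry
substantial posterior uncertainty — the template rule depends on them
only through the TMRCA ranking, which is much more stable.

## Numerical choices and degenerate inputs

* Ties and degeneracies: argmax ties break by the HWE rule above;
  zero-distance leaves may attach at time 0 in the consensus; a cohort
  with every site measured passes through the pipeline with an empty
  masked set.
* The four-gamete screen for real (recombined) data retains a maximal
  compatible site subset greedily left-to-right; the exact maximum
  independent set is NP-hard and the greedy rule matches the usual
  "exclude incompatible sites" practice.
* Monomorphic columns contribute no skeleton constraint; columns
  incompatible with a proposed tree have likelihood zero by contract
  rather than raising an error inside the sampler.
* All file formats are plain text: IMPUTE hap/legend/sample, phased VCF
  (strictly "|"-separated genotypes; "/" is a parse error), IMPUTE2-style
  .gen probability triplets, Newick tree samples (branch lengths in
  internal units), TSV results, YAML scenario configs.
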