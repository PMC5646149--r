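Package: coalimpute
Title: Coalescent-Based Genotype Imputation Within LD-Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype imputation for low-recombination regions (LD-blocks)
    that relies on the coalescent instead of current linkage-disequilibrium
    patterns. Haplotype cohorts are simulated under the basic Kingman
    coalescent and two demographic extensions (exponential growth and a
    clean population split); posterior gene genealogies are sampled by
    Markov chain Monte Carlo restricted to refinements of the
    perfect-phylogeny skeleton implied by the measured sites; sampled trees
    are collapsed into a majority-rule consensus tree annotated with mean
    posterior coalescence times; masked alleles are imputed from the
    reference haplotypes that first coalesce with each study haplotype.
    A diploid Li-Stephens haplotype-copying hidden Markov model evaluated
    at recombination rate zero is included as the standard comparator,
    together with evaluation utilities (genotype concordance, the
    chance-corrected imputation quality score, minor-allele-frequency
    stratification and replicate summaries).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
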