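#' Scenario configuration for the full imputation pipeline
#'
#' Bundles the simulation design, demography, inference settings and
#' replicate structure of one experiment. The default values reproduce the
#' baseline scenario: 1000 haplotypes (800 study + 200 reference) carrying
#' 100 polymorphic sites over 20 kb with N_e = 10,000 and
#' mu = 1.25e-8, 10 directly measured sites, 10 simulation replicates
#' crossed with 10 independent site selections, and 1000 MCMC trees per
#' configuration.
#'
#' @param n_haplotypes,n_sites,seq_length_bp,mu,study_fraction,measured_fraction
#'   see [sim_config].
#' @param n_e,alpha,growth_onset_years,beta,split_time_years,generation_time_years
#'   see [demography_model]; year-based times are converted with
#'   `generation_time_years`.
#' @param n_sim_replicates,n_site_selections replicate counts (>= 1).
#' @param methods character subset of `c("coalescent", "hmm")`.
#' @param n_trees,burn_in,thin MCMC settings for the coalescent method.
#' @param theta_prior length-2 lower/upper bounds of the uniform theta
#'   prior.
#' @param delta_generations template co-coalescence window (generations).
#' @param infer_mode demographic mode used for genealogy inference;
#'   `"auto"` matches the simulated demography.
#' @param seed master scenario seed; all stage seeds derive from it via
#'   [child_seed].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_haplotypes = 1000L,
                            n_sites = 100L,
                            seq_length_bp = 20000L,
                            mu = 1.25e-8,
                            n_e = 10000,
                            alpha = 0,
                            growth_onset_years = 5000,
                            beta = 1L,
                            split_time_years = 50000,
                            generation_time_years = 25,
                            alpha_per_generation = FALSE,
                            study_fraction = 0.8,
                            measured_fraction = 0.1,
                            n_sim_replicates = 10L,
                            n_site_selections = 10L,
                            methods = c("coalescent", "hmm"),
                            n_trees = 1000L,
                            burn_in = NULL,
                            thin = 5L,
                            theta_prior = c(0, 100),
                            delta_generations = 10,
                            infer_mode = "auto",
                            seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_sim_replicates < 1L || n_site_selections < 1L)
    stop("replicate counts must be >= 1")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_sites = as.integer(n_sites),
                 seq_length_bp = as.integer(seq_length_bp),
                 mu = mu, n_e = n_e, alpha = alpha,
                 alpha_per_generation = alpha_per_generation,
                 growth_onset_years = growth_onset_years,
                 beta = as.integer(beta),
                 split_time_years = split_time_years,
                 generation_time_years = generation_time_years,
                 study_fraction = study_fraction,
                 measured_fraction = measured_fraction,
                 n_sim_replicates = as.integer(n_sim_replicates),
                 n_site_selections = as.integer(n_site_selections),
                 methods = methods,
                 n_trees = as.integer(n_trees),
                 burn_in = burn_in, thin = as.integer(thin),
                 theta_prior = theta_prior,
                 delta_generations = delta_generations,
                 infer_mode = infer_mode,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

## demography implied by a scenario configuration. Growth coefficients in
## scenario tables follow the coalescent-scaled convention of ms-family
## simulators (rate per 4 N_e generations, so the per-generation rate is
## alpha / (4 N_e)); set alpha_per_generation = TRUE to bypass the scaling.
scenario_demography <- function(cfg) {
  a_gen <- if (isTRUE(cfg$alpha_per_generation)) cfg$alpha
           else cfg$alpha / (4 * cfg$n_e)
  demography_model(
    n_e = cfg$n_e,
    growth_rate_alpha = a_gen,
    growth_onset_generations =
      if (cfg$alpha > 0)
        years_to_generations(cfg$growth_onset_years,
                             cfg$generation_time_years) else 0,
    n_subpops_beta = cfg$beta,
    split_time_generations =
      if (cfg$beta > 1L)
        years_to_generations(cfg$split_time_years,
                             cfg$generation_time_years) else 0,
    subpop_hap_counts =
      if (cfg$beta > 1L) rep(cfg$n_haplotypes %/% cfg$beta, cfg$beta)
      else NULL,
    generation_time_years = cfg$generation_time_years)
}

## inference mode implied by a scenario ("auto" follows the simulation)
scenario_mode <- function(cfg) {
  if (cfg$infer_mode != "auto") return(cfg$infer_mode)
  if (cfg$alpha > 0 && cfg$beta > 1L) "growth-structure"
  else if (cfg$alpha > 0) "growth"
  else if (cfg$beta > 1L) "structure"
  else "basic"
}

#' Run one simulated replicate of the pipeline
#'
#' Simulates a cohort from the given seeds, imputes the masked genotypes
#' with the requested methods on the identical cohort, and evaluates both
#' against the held-out truth.
#'
#' @param cfg a `scenario_config`.
#' @param seed_sim,seed_sites seeds for haplotype simulation and measured
#'   site selection.
#' @return named list of evaluation tables (one per method, see
#'   [evaluate_imputation]), with the cohort attached as attribute.
#' @export
run_replicate <- function(cfg, seed_sim, seed_sites) {
  demog <- scenario_demography(cfg)
  scfg <- sim_config(n_haplotypes = cfg$n_haplotypes,
                     n_sites_S = cfg$n_sites,
                     seq_length_bp_L = cfg$seq_length_bp,
                     mu_per_site = cfg$mu,
                     study_fraction = cfg$study_fraction,
                     measured_fraction = cfg$measured_fraction,
                     seed_sim = seed_sim, seed_sites = seed_sites)
  cohort <- simulate_cohort(scfg, demog)
  out <- list()
  if ("coalescent" %in% cfg$methods) {
    set.seed(child_seed(seed_sim, seed_sites, 101L))
    meas <- subset_sites(cohort$haps, cohort$measured)
    priors <- prior_config(theta_lower = cfg$theta_prior[1L],
                           theta_upper = cfg$theta_prior[2L])
    ts <- mcmc_sample(meas, priors = priors, demography = demog,
                      mode = scenario_mode(cfg),
                      n_samples = cfg$n_trees,
                      burn_in = cfg$burn_in, thin = cfg$thin,
                      leaf_deme = cohort$leaf_deme)
    cons <- consensus_from_sample(ts)
    rule <- template_rule(cfg$delta_generations, cfg$n_e)
    post <- impute_cohort_coalescent(cohort, cons, rule)
    out$coalescent <- evaluate_imputation(cohort, post)
  }
  if ("hmm" %in% cfg$methods) {
    post <- impute_cohort_hmm(cohort)
    out$hmm <- evaluate_imputation(cohort, post)
  }
  attr(out, "cohort") <- cohort
  out
}

#' Run a full scenario: replicate loops, both methods, aggregation
#'
#' Outer loop over simulation seeds, inner loop over site-selection seeds
#' (both derived from the scenario seed via [child_seed]); each cell runs
#' the configured imputation methods on an identical cohort. Per-replicate
#' concordance and IQS values are aggregated with [summarize_replicates]
#' into one row per (method, MAF category) — the layout of the simulation
#' results tables.
#'
#' @param cfg a `scenario_config`.
#' @param verbose print progress lines.
#' @return list with `table` (aggregated data.frame: method, maf_category,
#'   n_variants, mean_concordance, ci_lo, ci_hi, mean_iqs) and `replicates`
#'   (per-cell evaluation tables).
#' @export
run_scenario <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  cells <- list()
  for (r in seq_len(cfg$n_sim_replicates)) {
    for (s in seq_len(cfg$n_site_selections)) {
      seed_sim <- child_seed(cfg$seed, 1L, r)
      seed_sites <- child_seed(cfg$seed, 2L, r, s)
      if (verbose)
        message(sprintf("replicate %d / site selection %d", r, s))
      res <- tryCatch(
        run_replicate(cfg, seed_sim, seed_sites),
        error = function(e) stop(sprintf(
          "scenario failed at simulation replicate %d, site selection %d: %s",
          r, s, conditionMessage(e)), call. = FALSE))
      attr(res, "cohort") <- NULL
      cells[[length(cells) + 1L]] <- res
    }
  }
  rows <- list()
  for (method in cfg$methods) {
    per <- lapply(cells, `[[`, method)
    for (cat in c("all", "rare", "low-frequency", "common")) {
      conc <- vapply(per, function(tb)
        tb$concordance[tb$maf_category == cat], 0)
      iq <- vapply(per, function(tb) tb$iqs[tb$maf_category == cat], 0)
      nv <- vapply(per, function(tb)
        tb$n_variants[tb$maf_category == cat], 0L)
      sm <- summarize_replicates(conc)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, maf_category = cat,
                   n_variants = mean(nv),
                   mean_concordance = sm$mean,
                   ci_lo = sm$ci_lo, ci_hi = sm$ci_hi,
                   mean_iqs = mean(iq, na.rm = TRUE))
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, replicates = cells)
}
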